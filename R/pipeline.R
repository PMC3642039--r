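#' Default pipeline configuration
#'
#' Builds the demo configuration: a small seeded simulation, default
#' thresholds, detector settings sized for a quick end-to-end run, and an
#' output directory. Exactly one of `input_path` / `simulation` may be set.
#'
#' @param out_dir output directory.
#' @param seed global integer seed; per-stage child seeds are derived
#'   deterministically from it.
#' @param input_path optional wide TSV consumed instead of simulating.
#' @param simulation named list of [simulation_spec()] arguments.
#' @param thresholds_ a [thresholds()] list.
#' @param n_scrambles permutation count for the cosine detector.
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(out_dir = tempfile("rhythmscan_run_"),
                       seed = 1L, input_path = NULL,
                       simulation = list(n_sinusoidal = 30, n_pulsatile = 5,
                                         n_arrhythmic = 45, n_type_I = 5,
                                         n_type_II = 5, n_type_III = 5,
                                         period_hr = 24, sigma = 0.1),
                       thresholds_ = thresholds(),
                       n_scrambles = 200) {
  if (!is.null(input_path) && !is.null(simulation))
    stop("specify exactly one of 'input_path' or 'simulation'")
  if (is.null(input_path) && is.null(simulation))
    stop("specify one of 'input_path' or 'simulation'")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 input_path = input_path, simulation = simulation,
                 thresholds = thresholds_, n_scrambles = n_scrambles),
            class = "RunConfig")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with `run_config()` fields.
#' @return a `RunConfig` list.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- if (!is.null(raw$thresholds)) do.call(thresholds, raw$thresholds)
        else thresholds()
  sim <- if (!is.null(raw$input_path) && !is.null(raw$simulation))
    raw$simulation  # let run_config() raise the both-specified error
  else if (!is.null(raw$input_path)) NULL
  else raw$simulation %||% formals(run_config)$simulation
  if (is.call(sim) || is.pairlist(sim)) sim <- eval(sim)
  run_config(out_dir = raw$out_dir %||% tempfile("rhythmscan_run_"),
             seed = raw$seed %||% 1L,
             input_path = raw$input_path,
             simulation = sim,
             thresholds_ = th,
             n_scrambles = raw$n_scrambles %||% 200)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable per-stage child seed below 2^31
.child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2000000000L
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> intensity filter -> four detectors -> consensus ->
#' downstream summaries -> promoter scan -> optional cross-species
#' comparison, writing every stage output as TSV plus a JSON manifest with
#' seed, config hash and per-file MD5 checksums. Rerunning the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a [run_config()] list, or a path to a JSON config.
#' @return the manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  th <- config$thresholds

  # --- simulate or load -----------------------------------------------
  if (!is.null(config$simulation)) {
    spec <- do.call(simulation_spec,
                    c(config$simulation,
                      list(seed = .child_seed(config$seed, "simulate"))))
    sim <- simulate_ld_dd_pair(spec)
    tc_ld <- sim$ld; tc_dd <- sim$dd
    files["truth"] <- .write_tsv(sim$truth,
                                 file.path(config$out_dir, "truth.tsv"))
    files["matrix_ld"] <- write_time_course(
      tc_ld, file.path(config$out_dir, "matrix_ld.tsv"))
    files["matrix_dd"] <- write_time_course(
      tc_dd, file.path(config$out_dir, "matrix_dd.tsv"))
  } else {
    tc_ld <- read_time_course(config$input_path, regime = "LD")
    tc_dd <- NULL
  }

  # --- prefilter + detectors ------------------------------------------
  keep <- intensity_filter(tc_ld, th$intensity_floor)
  tc <- subset_probes(tc_ld, keep)
  cos_cfg <- cosopt_config(n_scrambles = config$n_scrambles,
                           seed = .child_seed(config$seed, "cosopt"))
  cosopt <- run_cosopt(tc, cos_cfg)
  jtk <- run_jtk(tc)
  dft <- run_dft(tc)
  pulse <- call_pulsatile(tc, c_min = th$pulse_c_min,
                          fold_min = th$pulse_fold_min)
  files["cosopt"] <- .write_tsv(cosopt,
                                file.path(config$out_dir, "cosopt.tsv"))
  files["jtk"] <- .write_tsv(jtk, file.path(config$out_dir, "jtk.tsv"))
  files["dft"] <- .write_tsv(dft, file.path(config$out_dir, "dft.tsv"))
  files["pulse"] <- .write_tsv(pulse,
                               file.path(config$out_dir, "pulse.tsv"))

  # --- consensus -------------------------------------------------------
  venn <- venn_partition(cosopt, jtk, dft, th)
  files["consensus"] <- .write_tsv(
    venn$results, file.path(config$out_dir, "consensus.tsv"))
  files["venn_counts"] <- .write_tsv(
    data.frame(region = names(venn$counts), n = venn$counts),
    file.path(config$out_dir, "venn_counts.tsv"))
  files["sweep"] <- .write_tsv(
    threshold_sweep(cosopt, jtk, dft),
    file.path(config$out_dir, "threshold_sweep.tsv"))

  # --- downstream ------------------------------------------------------
  rhythmic <- jtk[jtk$statistic < th$jtk_q_max & jtk$in_window, ]
  files["phase_distribution"] <- .write_tsv(
    phase_distribution(rhythmic),
    file.path(config$out_dir, "phase_distribution.tsv"))
  if (!is.null(tc_dd)) {
    fold <- ld_dd_fold(tc_ld, tc_dd, probes = rhythmic$probe_id)
    files["ld_dd_fold"] <- .write_tsv(
      fold$table, file.path(config$out_dir, "ld_dd_fold.tsv"))
    jtk_dd <- run_jtk(subset_probes(tc_dd, keep))
    prof_ld <- apply(tc_ld$intensities, c(1, 2), mean)
    prof_dd <- apply(tc_dd$intensities, c(1, 2), mean)
    types <- vapply(keep, function(pid) {
      i_ld <- match(pid, tc_ld$probe_ids)
      i_dd <- match(pid, tc_dd$probe_ids)
      classify_ld_dd_type(
        prof_ld[i_ld, ], prof_dd[i_dd, ],
        rhythmic_ld = pid %in% rhythmic$probe_id,
        rhythmic_dd = {
          r <- jtk_dd[jtk_dd$probe_id == pid, ]
          nrow(r) == 1 && r$statistic < th$jtk_q_max && r$in_window
        },
        t_hr = time_hours(tc_ld))
    }, "")
    files["ld_dd_types"] <- .write_tsv(
      data.frame(probe_id = keep, type = types),
      file.path(config$out_dir, "ld_dd_types.tsv"))
  }

  # --- promoter scan on simulated upstream regions ---------------------
  motifs <- motif_definitions()
  prom <- simulate_promoters(
    n = 5, length = 2000,
    planted = data.frame(seq = c(1, 2, 3),
                         motif = c("E_box_canonical", "CRE", "W_box"),
                         pattern = c("CACGTG", "TGACGTCA", "TTGACC"),
                         pos = c(-1200, -300, -1500),
                         strand = c("+", "-", "+"),
                         stringsAsFactors = FALSE),
    seed = .child_seed(config$seed, "promoters"))
  hits <- scan_promoters(prom$sequences, motifs)
  files["motif_hits"] <- .write_tsv(
    hits, file.path(config$out_dir, "motif_hits.tsv"))
  files["motif_counts"] <- .write_tsv(
    tabulate_hits(hits, stats::setNames(
      rep(2000L, length(prom$sequences)), names(prom$sequences))),
    file.path(config$out_dir, "motif_counts.tsv"))

  # --- manifest --------------------------------------------------------
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rhythmscan")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    files = as.list(stats::setNames(
      unname(tools::md5sum(unname(files))), names(files))))
  unlink(tmp)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/scripts/rhythmscan` wrapper:
#' `rhythmscan all --config cfg.json [--out dir] [--seed n]` runs the full
#' pipeline; `simulate` writes only the synthetic matrices. Individual
#' stages consume the files written by earlier stages via the pipeline
#' outputs.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: rhythmscan <all|simulate> [--config cfg.json]",
        "[--out dir] [--seed n]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  cfg <- if (!is.null(getopt("--config")))
    read_run_config(getopt("--config")) else run_config()
  if (!is.null(getopt("--out"))) cfg$out_dir <- getopt("--out")
  if (!is.null(getopt("--seed"))) cfg$seed <- as.integer(getopt("--seed"))
  if (cmd == "all") {
    run_pipeline(cfg)
  } else if (cmd == "simulate") {
    spec <- do.call(simulation_spec,
                    c(cfg$simulation,
                      list(seed = .child_seed(cfg$seed, "simulate"))))
    sim <- simulate_ld_dd_pair(spec)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_time_course(sim$ld, file.path(cfg$out_dir, "matrix_ld.tsv"))
    write_time_course(sim$dd, file.path(cfg$out_dir, "matrix_dd.tsv"))
    .write_tsv(sim$truth, file.path(cfg$out_dir, "truth.tsv"))
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
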
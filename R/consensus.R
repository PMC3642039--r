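#' Venn partition of detector calls
#'
#' Flags each probe per detector at the stated thresholds — cosine fit
#' (mean pMMCbeta below `cosopt_p_max` AND replicate best periods inside the
#' window), rank test (q below `jtk_q_max` AND period in window), DFT
#' (`s_mean` above `dft_s_min`; no period window, the statistic targets the
#' 24-h bin directly) — and assigns each probe to one of the 7 Venn regions
#' or "none". Period-window eligibility lives inside each detector's flag.
#'
#' @param cosopt output of [run_cosopt()].
#' @param jtk output of [run_jtk()].
#' @param dft output of [run_dft()].
#' @param th a [thresholds()] object.
#' @return list with `results` (data.frame `probe_id`, `cosopt`, `jtk`,
#'   `dft` logical flags, `region`) and `counts` (named integer vector over
#'   the 7 regions plus `none`; sums to the universe size).
#' @export
venn_partition <- function(cosopt, jtk, dft, th = thresholds()) {
  ids <- sort(cosopt$probe_id)
  if (!identical(ids, sort(jtk$probe_id)) ||
      !identical(ids, sort(dft$probe_id))) {
    asym <- unique(c(setdiff(cosopt$probe_id, jtk$probe_id),
                     setdiff(jtk$probe_id, cosopt$probe_id),
                     setdiff(cosopt$probe_id, dft$probe_id),
                     setdiff(dft$probe_id, cosopt$probe_id)))
    stop("detector outputs cover different probe universes; asymmetric: ",
         paste(utils::head(asym, 10), collapse = ", "))
  }
  co <- cosopt[match(ids, cosopt$probe_id), ]
  jt <- jtk[match(ids, jtk$probe_id), ]
  df_ <- dft[match(ids, dft$probe_id), ]
  f_c <- co$statistic < th$cosopt_p_max & co$in_window
  f_j <- jt$statistic < th$jtk_q_max & jt$in_window
  f_d <- df_$statistic > th$dft_s_min
  region <- rep("none", length(ids))
  lab <- c("COSOPT", "JTK", "DFT")
  for (i in seq_along(ids)) {
    on <- c(f_c[i], f_j[i], f_d[i])
    if (any(on)) region[i] <- paste(lab[on], collapse = "+")
  }
  region_levels <- c("COSOPT", "JTK", "DFT", "COSOPT+JTK", "COSOPT+DFT",
                     "JTK+DFT", "COSOPT+JTK+DFT", "none")
  counts <- table(factor(region, levels = region_levels))
  list(results = data.frame(probe_id = ids, cosopt = f_c, jtk = f_j,
                            dft = f_d, region = region,
                            stringsAsFactors = FALSE),
       counts = stats::setNames(as.integer(counts), region_levels))
}

#' Newly rhythmic probes relative to a prior call set
#'
#' Triple-overlap (consensus-rhythmic) probes minus a prior set, e.g. the
#' probes called at an earlier, stricter cosine-fit criterion
#' (pMMCbeta < 0.1).
#'
#' @param consensus output of [venn_partition()].
#' @param prior_set character vector of previously called probe ids.
#' @return character vector of newly rhythmic probe ids.
#' @export
newly_rhythmic <- function(consensus, prior_set) {
  triple <- consensus$results$probe_id[
    consensus$results$region == "COSOPT+JTK+DFT"]
  setdiff(triple, prior_set)
}

#' Rhythmic-probe counts across cutoff grids
#'
#' Counts rhythmic probes per detector at each cutoff in the supplied
#' grids, mirroring the study's threshold-sweep supplementary table
#' (period-window eligibility included for the cosine and rank detectors).
#' Counts are monotone in cutoff laxity.
#'
#' @param cosopt,jtk,dft detector outputs (as in [venn_partition()]).
#' @param cosopt_p_grid,jtk_q_grid,dft_s_grid numeric cutoff grids.
#' @return data.frame with columns `detector`, `cutoff`, `n_rhythmic`.
#' @export
threshold_sweep <- function(cosopt, jtk, dft,
                            cosopt_p_grid = c(0.05, 0.1, 0.2),
                            jtk_q_grid = c(0.05, 0.1),
                            dft_s_grid = c(0.3, 0.5)) {
  rows <- list()
  for (p in cosopt_p_grid)
    rows[[length(rows) + 1]] <- data.frame(
      detector = "COSOPT", cutoff = p,
      n_rhythmic = sum(cosopt$statistic < p & cosopt$in_window))
  for (q in jtk_q_grid)
    rows[[length(rows) + 1]] <- data.frame(
      detector = "JTK", cutoff = q,
      n_rhythmic = sum(jtk$statistic < q & jtk$in_window))
  for (s in dft_s_grid)
    rows[[length(rows) + 1]] <- data.frame(
      detector = "DFT", cutoff = s, n_rhythmic = sum(dft$statistic > s))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
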
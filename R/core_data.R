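#' Construct a time-course expression matrix
#'
#' The central container for all detectors: a probe x timepoint x replicate
#' array of nonnegative fluorescence intensities on a regular sampling grid.
#' The study design is 13 timepoints at 4-hour spacing (48 h span) with two
#' replicates, collected under a light:dark cycle (LD, collection starting at
#' ZT 12) or constant darkness (DD, starting at CT 0), but the grid is
#' caller-defined.
#'
#' Internally time is measured in hours since collection start; phases are
#' reported on the ZT/CT scale in `[0, 24)` via `start_phase_hr`.
#'
#' @param intensities numeric array `(probe, timepoint, replicate)`, or a
#'   matrix `(probe, timepoint)` for a single replicate. All values must be
#'   finite and nonnegative.
#' @param probe_ids character vector of probe identifiers, one per row.
#' @param regime `"LD"` or `"DD"`.
#' @param start_phase_hr hour on the ZT/CT scale of the first timepoint.
#'   Defaults to 12 for LD and 0 for DD, matching the study design.
#' @param sampling_interval_hr hours between consecutive timepoints.
#'
#' @return An object of class `TimeCourseMatrix`: a list with elements
#'   `intensities`, `probe_ids`, `n_timepoints`, `n_replicates`,
#'   `sampling_interval_hr`, `regime`, `start_phase_hr`.
#' @export
TimeCourseMatrix <- function(intensities, probe_ids = NULL,
                             regime = c("LD", "DD"),
                             start_phase_hr = NULL,
                             sampling_interval_hr = 4) {
  regime <- match.arg(regime)
  if (is.null(start_phase_hr))
    start_phase_hr <- if (regime == "LD") 12 else 0
  if (is.matrix(intensities))
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a (probe, timepoint, replicate) array")
  storage.mode(intensities) <- "double"
  d <- dim(intensities)
  if (is.null(probe_ids)) {
    probe_ids <- dimnames(intensities)[[1]]
    if (is.null(probe_ids)) probe_ids <- sprintf("probe_%04d", seq_len(d[1]))
  }
  if (length(probe_ids) != d[1])
    stop("length(probe_ids) != number of probe rows")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids")
  if (d[1] > 0 && anyNA(intensities)) {
    bad <- unique(which(apply(is.na(intensities), 1, any)))
    warning(sprintf("dropping %d probe(s) with missing values: %s",
                    length(bad), paste(utils::head(probe_ids[bad], 5),
                                       collapse = ", ")))
    keep <- setdiff(seq_len(d[1]), bad)
    intensities <- intensities[keep, , , drop = FALSE]
    probe_ids <- probe_ids[keep]
    d <- dim(intensities)
  }
  if (d[1] > 0 && (any(!is.finite(intensities)) || any(intensities < 0))) {
    bad <- which(apply(intensities, 1, function(z) any(!is.finite(z) | z < 0)))
    stop(sprintf("negative or non-finite intensities in probe(s): %s",
                 paste(utils::head(probe_ids[bad], 5), collapse = ", ")))
  }
  if (d[3] < 1) stop("replicate count must be >= 1")
  dimnames(intensities) <- list(probe_ids, NULL, NULL)
  structure(list(
    intensities = intensities,
    probe_ids = as.character(probe_ids),
    n_timepoints = d[2],
    n_replicates = d[3],
    sampling_interval_hr = sampling_interval_hr,
    regime = regime,
    start_phase_hr = start_phase_hr
  ), class = "TimeCourseMatrix")
}

#' @export
print.TimeCourseMatrix <- function(x, ...) {
  cat(sprintf(
    "TimeCourseMatrix: %d probes x %d timepoints x %d replicate(s)\n",
    length(x$probe_ids), x$n_timepoints, x$n_replicates))
  cat(sprintf("  regime %s, start %s %g, every %g h (span %g h)\n",
              x$regime, if (x$regime == "LD") "ZT" else "CT",
              x$start_phase_hr, x$sampling_interval_hr,
              x$sampling_interval_hr * (x$n_timepoints - 1)))
  invisible(x)
}

#' Hours since collection start for each timepoint
#' @param tc a `TimeCourseMatrix`.
#' @return numeric vector of length `n_timepoints`.
#' @export
time_hours <- function(tc) {
  tc$sampling_interval_hr * (seq_len(tc$n_timepoints) - 1)
}

#' ZT/CT label of each timepoint, in `[0, 24)`
#' @param tc a `TimeCourseMatrix`.
#' @return numeric vector of length `n_timepoints`.
#' @export
zt_hours <- function(tc) {
  (tc$start_phase_hr + time_hours(tc)) %% 24
}

#' Subset a TimeCourseMatrix by probe id
#' @param tc a `TimeCourseMatrix`.
#' @param probes character vector of probe ids to keep (order preserved).
#' @return a `TimeCourseMatrix`.
#' @export
subset_probes <- function(tc, probes) {
  idx <- match(probes, tc$probe_ids)
  if (anyNA(idx))
    stop("unknown probe id(s): ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  tc$intensities <- tc$intensities[idx, , , drop = FALSE]
  tc$probe_ids <- tc$probe_ids[idx]
  tc
}

#' Detector thresholds for consensus calling
#'
#' Defaults are the study's least-stringent published cutoffs: cosine-fit
#' pMMCbeta < 0.2, rank-test q < 0.1, DFT s > 0.3, pulse c > 1.6 with
#' peak-to-trough fold change > 1.5, a period window of 20-28 h under LD or
#' 18.5-26.5 h under DD, and a mean-intensity floor of 20.
#'
#' @param cosopt_p_max,jtk_q_max,dft_s_min,pulse_c_min,pulse_fold_min scalar
#'   cutoffs per detector.
#' @param period_window_hr length-2 numeric `(low, high)` in hours.
#' @param intensity_floor minimum per-replicate mean fluorescent intensity.
#' @return a named list of class `Thresholds`.
#' @export
thresholds <- function(cosopt_p_max = 0.2, jtk_q_max = 0.1, dft_s_min = 0.3,
                       pulse_c_min = 1.6, pulse_fold_min = 1.5,
                       period_window_hr = c(20, 28), intensity_floor = 20) {
  stopifnot(length(period_window_hr) == 2,
            period_window_hr[1] < period_window_hr[2],
            all(is.finite(c(cosopt_p_max, jtk_q_max, dft_s_min, pulse_c_min,
                            pulse_fold_min, period_window_hr,
                            intensity_floor))))
  structure(list(cosopt_p_max = cosopt_p_max, jtk_q_max = jtk_q_max,
                 dft_s_min = dft_s_min, pulse_c_min = pulse_c_min,
                 pulse_fold_min = pulse_fold_min,
                 period_window_hr = period_window_hr,
                 intensity_floor = intensity_floor),
            class = "Thresholds")
}

#' Period window for a light regime
#'
#' 20-28 h for LD designs and 18.5-26.5 h for constant-condition (DD)
#' designs.
#' @param regime `"LD"` or `"DD"`.
#' @return length-2 numeric `(low, high)` in hours.
#' @export
period_window_for_regime <- function(regime = c("LD", "DD")) {
  regime <- match.arg(regime)
  if (regime == "LD") c(20, 28) else c(18.5, 26.5)
}

# wide-table column name for (timepoint hours, replicate)
.tc_colname <- function(hr, rep) sprintf("T%g_r%d", hr, rep)

#' Write a time course as a wide TSV
#'
#' Columns: `probe_id`, then `T<hr>_r<rep>` per (timepoint, replicate), plus
#' a header-comment-free plain table readable by [read_time_course()].
#' @param tc a `TimeCourseMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path) {
  hrs <- time_hours(tc)
  df <- data.frame(probe_id = tc$probe_ids, stringsAsFactors = FALSE)
  for (r in seq_len(tc$n_replicates))
    for (j in seq_len(tc$n_timepoints))
      df[[.tc_colname(hrs[j], r)]] <- tc$intensities[, j, r]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide expression table into a TimeCourseMatrix
#'
#' Expects a TSV/CSV with a probe-id column and one numeric column per
#' (timepoint, replicate) named `T<hr>_r<rep>` (the convention written by
#' [write_time_course()]), or an explicit `schema` mapping.
#'
#' @param path file path (tab- or comma-separated; separator sniffed from the
#'   header line unless given).
#' @param regime,start_phase_hr passed to [TimeCourseMatrix()].
#' @param schema optional list with `probe_col` (name of the id column) and
#'   `value_cols`, a data.frame with columns `name`, `time_hr`, `replicate`
#'   mapping table columns onto the grid. When `NULL` the `T<hr>_r<rep>`
#'   convention is parsed from the header.
#' @param sep field separator; default sniffed.
#' @return a validated `TimeCourseMatrix`.
#' @export
read_time_course <- function(path, regime = c("LD", "DD"),
                             start_phase_hr = NULL, schema = NULL,
                             sep = NULL) {
  regime <- match.arg(regime)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(schema)) {
    cols <- setdiff(names(df), "probe_id")
    m <- regmatches(cols, regexec("^T([0-9.]+)_r([0-9]+)$", cols))
    ok <- lengths(m) == 3
    if (!("probe_id" %in% names(df)) || !any(ok))
      stop("expected a 'probe_id' column and T<hr>_r<rep> value columns; ",
           "found: ", paste(utils::head(names(df), 8), collapse = ", "))
    value_cols <- data.frame(
      name = cols[ok],
      time_hr = as.numeric(vapply(m[ok], `[`, "", 2)),
      replicate = as.integer(vapply(m[ok], `[`, "", 3)),
      stringsAsFactors = FALSE)
    schema <- list(probe_col = "probe_id", value_cols = value_cols)
  }
  vc <- schema$value_cols
  missing_cols <- setdiff(c(schema$probe_col, vc$name), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  hrs <- sort(unique(vc$time_hr))
  reps <- sort(unique(vc$replicate))
  if (nrow(vc) != length(hrs) * length(reps))
    stop("ragged table: value columns do not form a full ",
         "timepoint x replicate grid")
  n <- nrow(df)
  arr <- array(NA_real_, dim = c(n, length(hrs), length(reps)))
  for (k in seq_len(nrow(vc))) {
    v <- df[[vc$name[k]]]
    if (!is.numeric(v))
      stop("non-numeric cells in column '", vc$name[k], "'")
    arr[, match(vc$time_hr[k], hrs), match(vc$replicate[k], reps)] <- v
  }
  neg <- which(apply(arr, 1, function(z) any(is.finite(z) & z < 0)))
  if (length(neg))
    stop("negative intensity in row(s) for probe(s): ",
         paste(utils::head(df[[schema$probe_col]][neg], 5), collapse = ", "))
  iv <- if (length(hrs) > 1) diff(hrs)[1] else 4
  if (length(hrs) > 2 && any(abs(diff(hrs) - iv) > 1e-9))
    stop("timepoints are not on a regular grid: ", paste(hrs, collapse = ", "))
  TimeCourseMatrix(arr, probe_ids = df[[schema$probe_col]], regime = regime,
                   start_phase_hr = start_phase_hr,
                   sampling_interval_hr = iv)
}

#' Mean-intensity prefilter
#'
#' Keeps probes whose arithmetic mean intensity across all timepoints exceeds
#' `floor` in every replicate ("mean fluorescent intensity > 20 ... in both
#' replicates").
#'
#' @param tc a `TimeCourseMatrix`.
#' @param floor nonnegative intensity floor (default 20).
#' @return character vector of retained probe ids (a subset of
#'   `tc$probe_ids`, original order).
#' @export
intensity_filter <- function(tc, floor = 20) {
  stopifnot(floor >= 0)
  rep_means <- apply(tc$intensities, c(1, 3), mean)  # probe x replicate
  keep <- apply(rep_means > floor, 1, all)
  tc$probe_ids[keep]
}
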
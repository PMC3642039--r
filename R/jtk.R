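#' Configuration for the rank-correlation (JTK-style) detector
#'
#' Candidate periods default to 20-28 h in sampling-interval steps (20, 24,
#' 28 on the 4-h study grid); the phase lattice covers every sampling offset
#' within one period. The algorithm is deterministic.
#'
#' @param period_grid_hr candidate periods in hours; each must be a multiple
#'   of the sampling interval.
#' @param q_max q-value cutoff used by callers (default 0.05).
#' @param sampling_interval_hr grid spacing used to build the phase lattice.
#' @return a list of class `JtkConfig`.
#' @export
jtk_config <- function(period_grid_hr = c(20, 24, 28), q_max = 0.05,
                       sampling_interval_hr = 4) {
  stopifnot(length(period_grid_hr) >= 1,
            all(abs(period_grid_hr / sampling_interval_hr -
                    round(period_grid_hr / sampling_interval_hr)) < 1e-9))
  structure(list(period_grid_hr = period_grid_hr, q_max = q_max,
                 sampling_interval_hr = sampling_interval_hr),
            class = "JtkConfig")
}

# pairwise sign vector over all i<j pairs of v
.pair_signs <- function(v, idx) sign(v[idx[, 2]] - v[idx[, 1]])

# tie-correction terms for the Kendall S variance
.tie_terms <- function(v) {
  t_ <- table(v); t_ <- as.numeric(t_[t_ > 1])
  c(v0 = sum(t_ * (t_ - 1) * (2 * t_ + 5)),
    v1 = sum(t_ * (t_ - 1)),
    v2 = sum(t_ * (t_ - 1) * (t_ - 2)))
}

# Precompute the (period, phase) lattice of reference cosines at times t_hr:
# sign matrix (n_pairs x K), per-ref tie terms, periods, phases, refs.
.jtk_lattice <- function(t_hr, config) {
  n <- length(t_hr)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  periods <- phases <- numeric(0)
  refs <- list()
  for (tau in config$period_grid_hr) {
    for (phi in seq(0, tau - config$sampling_interval_hr,
                    by = config$sampling_interval_hr)) {
      periods <- c(periods, tau); phases <- c(phases, phi)
      refs[[length(refs) + 1]] <- cos(2 * pi * (t_hr - phi) / tau)
    }
  }
  # rounding guards against cos() noise splitting genuinely tied values
  refs <- lapply(refs, round, digits = 9)
  sr <- vapply(refs, .pair_signs, numeric(nrow(idx)), idx = idx)
  tie_r <- vapply(refs, .tie_terms, numeric(3))
  list(n = n, idx = idx, sr = sr, tie_r = tie_r,
       periods = periods, phases = phases, refs = refs,
       K = length(refs))
}

#' Rank-correlation rhythm test for a single probe
#'
#' Correlates the observed series (replicates concatenated with repeated
#' time labels, so one statistic per probe) against reference cosines on a
#' period x phase lattice using Kendall's S. The one-sided p-value comes
#' from the normal approximation of the Jonckheere-Terpstra/Kendall null
#' with tie correction and a continuity correction of 1; the minimum p over
#' the lattice is Bonferroni adjusted for the number of lattice points.
#' Amplitude is the median sign-adjusted deviation from the median with
#' respect to the optimal cosine pattern (equal to the cosine
#' amplitude / sqrt(2) in the continuous-sampling limit).
#'
#' @param x numeric series: replicate series concatenated.
#' @param t_hr time labels (hours since start) matching `x`; repeated across
#'   replicates.
#' @param config a [jtk_config()].
#' @param lattice precomputed internal lattice (used by [run_jtk()]).
#' @return list with `p` (Bonferroni-adjusted minimum p), `p_raw`,
#'   `period_hr`, `phase_hr` (peak, hours since start), `tau` (Kendall
#'   correlation at the optimum), `amplitude`.
#' @export
jtk_single <- function(x, t_hr, config = jtk_config(), lattice = NULL) {
  stopifnot(length(x) == length(t_hr))
  if (length(unique(x)) == 1L)
    return(list(p = 1, p_raw = 1, period_hr = NA_real_,
                phase_hr = NA_real_, tau = NA_real_, amplitude = 0))
  if (is.null(lattice)) lattice <- .jtk_lattice(t_hr, config)
  n <- lattice$n
  sx <- .pair_signs(x, lattice$idx)
  S <- as.vector(crossprod(lattice$sr, sx))
  tx <- .tie_terms(x)
  v0 <- n * (n - 1) * (2 * n + 5)
  vars <- (v0 - tx["v0"] - lattice$tie_r["v0", ]) / 18 +
    tx["v1"] * lattice$tie_r["v1", ] / (2 * n * (n - 1)) +
    tx["v2"] * lattice$tie_r["v2", ] / (9 * n * (n - 1) * (n - 2))
  pvals <- ifelse(vars <= 0, 1,
                  stats::pnorm((S - 1) / sqrt(pmax(vars, 0)),
                               lower.tail = FALSE))
  ord <- order(pvals, abs(lattice$periods - 24), lattice$phases)
  k <- ord[1]
  sr_k <- lattice$sr[, k]
  n_pairs <- sum(sr_k != 0)
  tau_cor <- if (n_pairs > 0)
    S[k] / sqrt(sum(sx != 0) * n_pairs) else NA_real_
  rf <- lattice$refs[[k]]
  amp <- stats::median((x - stats::median(x)) *
                         sign(rf - stats::median(rf)))
  list(p = min(1, lattice$K * pvals[k]), p_raw = pvals[k],
       period_hr = lattice$periods[k], phase_hr = lattice$phases[k],
       tau = tau_cor, amplitude = amp)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values with monotonicity enforcement; order preserving.
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Run the rank-correlation detector over a time-course matrix
#'
#' Replicates are concatenated with duplicated time labels (one q-value per
#' probe); p-values are converted to BH q-values across probes, and the
#' period window of the matrix regime is recorded in `in_window`.
#'
#' @param tc a `TimeCourseMatrix` (normally already intensity-filtered).
#' @param config a [jtk_config()].
#' @param period_window_hr length-2 window; default from `tc$regime`.
#' @return data.frame: `probe_id`, `detector`, `statistic` (q), `p`,
#'   `period_hr`, `peak_phase_hr` (ZT/CT scale), `amplitude`, `tau`,
#'   `in_window`.
#' @export
run_jtk <- function(tc, config = jtk_config(), period_window_hr = NULL) {
  stopifnot(inherits(tc, "TimeCourseMatrix"))
  if (is.null(period_window_hr))
    period_window_hr <- period_window_for_regime(tc$regime)
  t_hr <- rep(time_hours(tc), times = tc$n_replicates)
  lattice <- .jtk_lattice(t_hr, config)
  n_probe <- length(tc$probe_ids)
  p <- period <- phase <- amp <- tau_c <- rep(NA_real_, n_probe)
  for (i in seq_len(n_probe)) {
    f <- jtk_single(as.vector(tc$intensities[i, , ]), t_hr, config, lattice)
    p[i] <- f$p; period[i] <- f$period_hr; phase[i] <- f$phase_hr
    amp[i] <- f$amplitude; tau_c[i] <- f$tau
  }
  res <- data.frame(
    probe_id = tc$probe_ids, detector = "JTK",
    statistic = bh_adjust(p), p = p, period_hr = period,
    peak_phase_hr = ifelse(is.na(phase), NA_real_,
                           (tc$start_phase_hr + phase) %% 24),
    amplitude = amp, tau = tau_c,
    in_window = !is.na(period) & period >= period_window_hr[1] &
      period <= period_window_hr[2],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
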
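#' Peak-phase distribution of rhythmic genes
#'
#' For genes with multiple rhythmic probes only the probe with the lowest
#' q-value is kept; phases are then binned on the 24-h ZT/CT clock with
#' right-closed bins ("up to and including the phase indicated") and
#' reported as percentages of rhythmic genes.
#'
#' @param calls output of [run_jtk()] restricted to rhythmic probes (or any
#'   data.frame with `probe_id`, `statistic`, `peak_phase_hr`).
#' @param gene_map named character vector or data.frame (`probe_id`,
#'   `gene_id`) mapping probes to genes; `NULL` treats each probe as its
#'   own gene.
#' @param bin_width_hr bin width in hours (24 must be a multiple; default 3).
#' @return data.frame with `bin_end_hr` (right edge, bins are
#'   `(end - width, end]` with phase 0 counted as 24), `n`, `percent`.
#'   Percentages sum to 100 up to rounding.
#' @export
phase_distribution <- function(calls, gene_map = NULL, bin_width_hr = 3) {
  stopifnot(24 %% bin_width_hr == 0)
  edges <- seq(bin_width_hr, 24, by = bin_width_hr)
  if (nrow(calls) == 0)
    return(data.frame(bin_end_hr = numeric(0), n = integer(0),
                      percent = numeric(0)))
  if (is.null(gene_map)) {
    calls$gene_id <- calls$probe_id
  } else if (is.data.frame(gene_map)) {
    calls$gene_id <- gene_map$gene_id[match(calls$probe_id,
                                            gene_map$probe_id)]
  } else {
    calls$gene_id <- unname(gene_map[calls$probe_id])
  }
  calls <- calls[order(calls$statistic), ]
  calls <- calls[!duplicated(calls$gene_id), ]   # lowest q per gene
  ph <- calls$peak_phase_hr %% 24
  ph[ph == 0] <- 24                              # right-closed circle
  bin <- ceiling(ph / bin_width_hr) * bin_width_hr
  n <- vapply(edges, function(e) sum(bin == e), 0L)
  data.frame(bin_end_hr = edges, n = n, percent = 100 * n / sum(n))
}

#' Peak/nadir amplitude with the 8-16 h interval rule
#'
#' Amplitude as peak divided by nadir intensity, valid only when the
#' peak-to-nadir separation on the time axis falls within the stated
#' window (8-16 h for a near-24-h rhythm). The ratio is reported
#' regardless and flagged.
#'
#' @param signal positive numeric profile.
#' @param t_hr sample times in hours (default 4-h grid).
#' @param window_hr length-2 admissible peak-to-nadir interval.
#' @return list: `peak`, `nadir`, `ratio`, `interval_hr`, `valid`, `reason`.
#' @export
peak_nadir_amplitude <- function(signal, t_hr = 4 * (seq_along(signal) - 1),
                                 window_hr = c(8, 16)) {
  i_pk <- which.max(signal); i_nd <- which.min(signal)
  peak <- signal[i_pk]; nadir <- signal[i_nd]
  interval <- abs(t_hr[i_pk] - t_hr[i_nd])
  if (nadir == 0)
    return(list(peak = peak, nadir = 0, ratio = NA_real_,
                interval_hr = interval, valid = FALSE,
                reason = "zero nadir: ratio undefined"))
  valid <- interval >= window_hr[1] & interval <= window_hr[2]
  list(peak = peak, nadir = nadir, ratio = peak / nadir,
       interval_hr = interval, valid = valid,
       reason = if (valid) "" else
         sprintf("peak-to-nadir interval %g h outside [%g, %g]",
                 interval, window_hr[1], window_hr[2]))
}

#' LD-vs-DD mean-expression fold change
#'
#' Per probe, the mean expression over the first 12 shared timepoints is
#' computed in each condition (replicates pooled) and the fold change
#' reported symmetrically as max/min with a direction flag; the summary is
#' the fraction of probes exceeding 2-fold.
#'
#' @param tc_ld,tc_dd `TimeCourseMatrix` objects sharing probes.
#' @param probes probe subset to analyze (e.g. the rhythmic set); default
#'   all probes common to both matrices. Probes missing in one condition
#'   are excluded with a message.
#' @param n_timepoints number of leading timepoints averaged (default 12).
#' @return list with `table` (data.frame `probe_id`, `mean_ld`, `mean_dd`,
#'   `fold`, `direction`) and `fraction_over_2fold`.
#' @export
ld_dd_fold <- function(tc_ld, tc_dd, probes = NULL, n_timepoints = 12) {
  if (is.null(probes)) probes <- tc_ld$probe_ids
  missing_ <- probes[!(probes %in% tc_ld$probe_ids &
                         probes %in% tc_dd$probe_ids)]
  if (length(missing_)) {
    message("ld_dd_fold: excluding ", length(missing_),
            " probe(s) absent in one condition")
    probes <- setdiff(probes, missing_)
  }
  i_ld <- match(probes, tc_ld$probe_ids)
  i_dd <- match(probes, tc_dd$probe_ids)
  tp <- seq_len(min(n_timepoints, tc_ld$n_timepoints, tc_dd$n_timepoints))
  m_ld <- apply(tc_ld$intensities[i_ld, tp, , drop = FALSE], 1, mean)
  m_dd <- apply(tc_dd$intensities[i_dd, tp, , drop = FALSE], 1, mean)
  fold <- pmax(m_ld, m_dd) / pmin(m_ld, m_dd)
  tab <- data.frame(probe_id = probes, mean_ld = m_ld, mean_dd = m_dd,
                    fold = fold,
                    direction = ifelse(m_ld >= m_dd, "LD-high", "DD-high"),
                    stringsAsFactors = FALSE)
  list(table = tab, fraction_over_2fold = mean(fold > 2))
}

#' Classify a probe's LD-to-DD transition pattern
#'
#' Operationalizes the three transition types: `III` when rhythmic under LD
#' but not DD with DD mean at or below the LD nadir; `II` when rhythmic
#' under LD and the first-DD-cycle subjective-day mean (CT 0-12) exceeds
#' the second-cycle subjective-day mean by `factor`; `I` when rhythmic in
#' both regimes with DD peak-to-trough amplitude below the LD amplitude;
#' `other` otherwise. Rule II is evaluated before rule I because type II
#' probes are themselves rhythmic in both regimes with reduced DD
#' amplitude and would otherwise be absorbed by rule I.
#'
#' @param ld_profile,dd_profile replicate-averaged 13-point profiles.
#' @param rhythmic_ld,rhythmic_dd logical rhythm calls per regime.
#' @param t_hr sample times (hours since start; DD starts at CT 0).
#' @param factor type II first/second subjective-day ratio (default 1.5).
#' @param tol numeric slack on the type III nadir comparison.
#' @return one of `"I"`, `"II"`, `"III"`, `"other"`.
#' @export
classify_ld_dd_type <- function(ld_profile, dd_profile, rhythmic_ld,
                                rhythmic_dd,
                                t_hr = 4 * (seq_along(ld_profile) - 1),
                                factor = 1.5, tol = 1e-8) {
  if (!isTRUE(rhythmic_ld)) return("other")
  ct <- t_hr %% 24
  day1 <- t_hr < 24 & ct <= 12
  day2 <- t_hr >= 24 & t_hr < 48 & ct <= 12
  if (!isTRUE(rhythmic_dd) &&
      mean(dd_profile) <= min(ld_profile) + tol)
    return("III")
  if (sum(day2) > 0 &&
      mean(dd_profile[day1]) > factor * mean(dd_profile[day2]))
    return("II")
  if (isTRUE(rhythmic_dd) &&
      diff(range(dd_profile)) < diff(range(ld_profile)))
    return("I")
  "other"
}

#' Hierarchical clustering of expression profiles
#'
#' Profiles are log2 transformed, mean centered and scaled to unit sum of
#' squares across the time course per probe, then agglomerated with
#' centroid linkage under correlation-based distance (1 - r on the
#' normalized vectors, the uncentered-correlation family of Cluster 3.0).
#' Only probes with mean intensity above `floor` are clustered.
#'
#' @param tc a `TimeCourseMatrix`; replicates are averaged.
#' @param probes optional probe subset.
#' @param floor mean-intensity floor (default 20).
#' @return list with `tree` (an `hclust`; `NULL` for a single probe),
#'   `matrix` (normalized probe x timepoint matrix in leaf order),
#'   `order` (probe ids in dendrogram order).
#' @export
hierarchical_cluster <- function(tc, probes = NULL, floor = 20) {
  if (is.null(probes)) probes <- tc$probe_ids
  keep <- intensity_filter(subset_probes(tc, probes), floor)
  m <- apply(subset_probes(tc, keep)$intensities, c(1, 2), mean)
  rownames(m) <- keep
  lm2 <- log2(m)
  lm2 <- lm2 - rowMeans(lm2)
  ss <- sqrt(rowSums(lm2^2))
  ss[ss == 0] <- 1
  lm2 <- lm2 / ss
  if (nrow(lm2) < 2)
    return(list(tree = NULL, matrix = lm2, order = rownames(lm2)))
  d <- stats::as.dist(1 - tcrossprod(lm2))   # 1 - correlation (unit vectors)
  tree <- stats::hclust(d, method = "centroid")
  list(tree = tree, matrix = lm2[tree$order, , drop = FALSE],
       order = rownames(lm2)[tree$order])
}

#' Z-score expression profiles
#'
#' Per probe, `(x - mean) / sd` across the time course on the
#' replicate-averaged profile; constant profiles map to all zeros with a
#' message.
#'
#' @param tc a `TimeCourseMatrix`.
#' @param probes optional probe subset.
#' @return numeric matrix (probe x timepoint) of standardized profiles.
#' @export
zscore_profiles <- function(tc, probes = NULL) {
  if (!is.null(probes)) tc <- subset_probes(tc, probes)
  m <- apply(tc$intensities, c(1, 2), mean)
  rownames(m) <- tc$probe_ids
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    message("zscore_profiles: ", sum(sds == 0),
            " constant profile(s) set to zero")
  out <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  out
}
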
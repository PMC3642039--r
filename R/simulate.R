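#' Specification for synthetic expression data
#'
#' The generator emulates the statistical structure the detectors assume:
#' nonnegative fluorescence-like intensities over 13 timepoints at 4-hour
#' spacing (48 h) with 2 replicates; a rhythmic fraction with sinusoidal
#' profiles, pulsatile probes with single-timepoint spikes recurring every
#' 24 h, arrhythmic probes, and (for paired LD/DD simulation) the three
#' light-regime transition patterns:
#' type I (rhythmic in LD and DD with DD amplitude scaled down), type II
#' (first DD cycle held at the LD daytime level during subjective day,
#' dampened thereafter) and type III (flat in DD at or below the LD nadir).
#'
#' Noise is multiplicative lognormal (`exp(rnorm(0, sigma))`), reflecting
#' positive, heteroskedastic fluorescence intensities. The default baseline
#' of 100 sits well above the intensity floor of 20 so the prefilter is not
#' exercised unless configured.
#'
#' @param n_sinusoidal,n_pulsatile,n_arrhythmic,n_type_I,n_type_II,n_type_III
#'   probe counts per class.
#' @param period_hr length-1 or length-2 numeric: a fixed sinusoid period or
#'   a `(low, high)` range sampled uniformly. Default `c(20, 28)`.
#' @param phase_hr length-1 or length-2 numeric: fixed peak phase (ZT/CT
#'   hours) or a range sampled uniformly on `[0, 24)`. Default `c(0, 24)`.
#' @param baseline mean intensity level (> 0).
#' @param rel_amplitude relative sinusoid amplitude A in
#'   `baseline * (1 + A cos(...))`.
#' @param spike_fold pulsatile spike height as a multiple of baseline.
#' @param sigma lognormal noise sigma (0 = noiseless).
#' @param dd_scale amplitude/level scaling for DD in type I/II probes.
#' @param n_timepoints,n_replicates,sampling_interval_hr grid (study default
#'   13 x 2 at 4 h).
#' @param seed integer seed; identical seeds give identical output.
#' @return a list of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_sinusoidal = 0, n_pulsatile = 0,
                            n_arrhythmic = 0, n_type_I = 0, n_type_II = 0,
                            n_type_III = 0,
                            period_hr = c(20, 28), phase_hr = c(0, 24),
                            baseline = 100, rel_amplitude = 0.5,
                            spike_fold = 3, sigma = 0.1, dd_scale = 0.25,
                            n_timepoints = 13, n_replicates = 2,
                            sampling_interval_hr = 4, seed = 1L) {
  counts <- c(n_sinusoidal, n_pulsatile, n_arrhythmic,
              n_type_I, n_type_II, n_type_III)
  stopifnot(all(counts >= 0), baseline > 0, sigma >= 0, dd_scale > 0,
            rel_amplitude >= 0, rel_amplitude < 1, spike_fold > 0)
  structure(as.list(environment()), class = "SimulationSpec")
}

.draw <- function(rng, n) {
  if (length(rng) == 1) rep(rng, n) else stats::runif(n, rng[1], rng[2])
}

.noise <- function(spec, n) {
  if (spec$sigma == 0) rep(1, n) else exp(stats::rnorm(n, 0, spec$sigma))
}

# sinusoid evaluated at ZT/CT hours zt
.sin_profile <- function(baseline, A, tau, phi, zt) {
  baseline * (1 + A * cos(2 * pi * (zt - phi) / tau))
}

#' Simulate a labelled expression matrix
#'
#' Generates sinusoidal, pulsatile and arrhythmic probes per the spec, with a
#' per-probe ground-truth table. Sinusoidal probe profiles follow
#' `baseline * (1 + A cos(2 pi (t - phi) / tau)) * noise`; pulsatile probes
#' are baseline plus a single elevated timepoint recurring every 24 h;
#' arrhythmic probes are `baseline * noise`.
#'
#' @param spec a [simulation_spec()].
#' @param regime `"LD"` or `"DD"` (sets the start phase: ZT 12 resp. CT 0).
#' @return list with `tc` (a `TimeCourseMatrix`) and `truth`, a data.frame
#'   with columns `probe_id`, `class`, `period_hr`, `phase_hr`,
#'   `rel_amplitude`.
#' @export
simulate_matrix <- function(spec, regime = c("LD", "DD")) {
  regime <- match.arg(regime)
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  start <- if (regime == "LD") 12 else 0
  nt <- spec$n_timepoints; nr <- spec$n_replicates
  t_hr <- spec$sampling_interval_hr * (seq_len(nt) - 1)
  zt <- (start + t_hr) %% 24
  n_all <- spec$n_sinusoidal + spec$n_pulsatile + spec$n_arrhythmic
  arr <- array(0, dim = c(n_all, nt, nr))
  truth <- data.frame(probe_id = character(0), class = character(0),
                      period_hr = numeric(0), phase_hr = numeric(0),
                      rel_amplitude = numeric(0), stringsAsFactors = FALSE)
  if (n_all == 0) {
    return(list(tc = TimeCourseMatrix(arr, character(0), regime = regime),
                truth = truth))
  }
  cls <- rep(c("sinusoidal", "pulsatile", "arrhythmic"),
             times = c(spec$n_sinusoidal, spec$n_pulsatile,
                       spec$n_arrhythmic))
  ids <- sprintf("%s_%04d", substr(cls, 1, 3), seq_len(n_all))
  tau <- phi <- amp <- rep(NA_real_, n_all)
  i_sin <- which(cls == "sinusoidal")
  tau[i_sin] <- .draw(spec$period_hr, length(i_sin))
  phi[i_sin] <- .draw(spec$phase_hr, length(i_sin)) %% 24
  amp[i_sin] <- spec$rel_amplitude
  for (i in i_sin) {
    # phase is on the absolute ZT/CT scale; evaluate the cosine on the
    # internal time axis so non-24 h periods advance correctly
    prof <- .sin_profile(spec$baseline, spec$rel_amplitude, tau[i],
                         phi[i] - start, t_hr)
    for (r in seq_len(nr)) arr[i, , r] <- prof * .noise(spec, nt)
  }
  i_pul <- which(cls == "pulsatile")
  spp <- round(24 / spec$sampling_interval_hr)  # samples per 24 h
  for (i in i_pul) {
    off <- sample.int(spp, 1) - 1L
    spike_at <- which((seq_len(nt) - 1 - off) %% spp == 0)
    prof <- rep(spec$baseline, nt)
    prof[spike_at] <- spec$baseline * spec$spike_fold
    phi[i] <- zt[spike_at[1]]
    tau[i] <- 24
    for (r in seq_len(nr)) arr[i, , r] <- prof * .noise(spec, nt)
  }
  for (i in which(cls == "arrhythmic"))
    for (r in seq_len(nr)) arr[i, , r] <- spec$baseline * .noise(spec, nt)
  truth <- data.frame(probe_id = ids, class = cls, period_hr = tau,
                      phase_hr = phi, rel_amplitude = amp,
                      stringsAsFactors = FALSE)
  list(tc = TimeCourseMatrix(arr, ids, regime = regime,
                             sampling_interval_hr = spec$sampling_interval_hr),
       truth = truth)
}

#' Simulate a paired LD/DD time-course exhibiting transition types
#'
#' Builds matched LD (start ZT 12) and DD (start CT 0) matrices. Sinusoidal,
#' pulsatile and arrhythmic probes behave identically in both regimes.
#' Transition-type probes are rhythmic under LD and behave as follows in DD:
#' type I keeps the rhythm with relative amplitude scaled by `dd_scale`;
#' type II holds the LD peak level during the first subjective day
#' (CT 0-12 of cycle 1) and is dampened to `dd_scale` of the LD level in
#' cycle 2; type III is flat at the LD nadir level.
#'
#' @param spec a [simulation_spec()].
#' @return list with `ld`, `dd` (`TimeCourseMatrix`) and `truth` (adds a
#'   `type` column: `I`, `II`, `III` or `none`).
#' @export
simulate_ld_dd_pair <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  base_sim <- simulate_matrix(spec, regime = "LD")
  set.seed(spec$seed + 1L)
  nt <- spec$n_timepoints; nr <- spec$n_replicates
  t_hr <- spec$sampling_interval_hr * (seq_len(nt) - 1)
  n_ty <- spec$n_type_I + spec$n_type_II + spec$n_type_III
  ty <- rep(c("I", "II", "III"),
            times = c(spec$n_type_I, spec$n_type_II, spec$n_type_III))
  ids_ty <- sprintf("type%s_%04d", ty, seq_len(n_ty))
  A <- spec$rel_amplitude
  tau_ty <- rep(24, n_ty)            # transition probes are 24-h diel rhythms
  phi_ty <- .draw(spec$phase_hr, n_ty) %% 24
  ld_ty <- array(0, dim = c(n_ty, nt, nr))
  dd_ty <- array(0, dim = c(n_ty, nt, nr))
  ct <- t_hr %% 24                    # DD starts at CT 0
  day1 <- which(t_hr < 24 & ct <= 12)          # first-cycle subjective day
  cycle2 <- which(t_hr >= 24 & t_hr < 48)
  for (i in seq_len(n_ty)) {
    ld_prof <- .sin_profile(spec$baseline, A, 24, phi_ty[i] - 12, t_hr)
    dd_prof <- switch(ty[i],
      I = .sin_profile(spec$baseline, A * spec$dd_scale, 24, phi_ty[i], t_hr),
      II = {
        p <- .sin_profile(spec$baseline * spec$dd_scale, A, 24,
                          phi_ty[i], t_hr)
        p[day1] <- spec$baseline * (1 + A)     # held at the LD peak level
        p
      },
      III = rep(spec$baseline * (1 - A), nt))  # flat at the LD nadir
    for (r in seq_len(nr)) {
      ld_ty[i, , r] <- ld_prof * .noise(spec, nt)
      dd_ty[i, , r] <- dd_prof * .noise(spec, nt)
    }
  }
  n_base <- length(base_sim$tc$probe_ids)
  ld_arr <- array(0, dim = c(n_base + n_ty, nt, nr))
  dd_arr <- ld_arr
  if (n_base > 0) {
    ld_arr[seq_len(n_base), , ] <- base_sim$tc$intensities
    # regime-shared probes: same generative law, fresh noise in DD
    set.seed(spec$seed + 2L)
    dd_base <- simulate_matrix(spec, regime = "DD")
    dd_arr[seq_len(n_base), , ] <- dd_base$tc$intensities
  }
  if (n_ty > 0) {
    ld_arr[n_base + seq_len(n_ty), , ] <- ld_ty
    dd_arr[n_base + seq_len(n_ty), , ] <- dd_ty
  }
  ids <- c(base_sim$tc$probe_ids, ids_ty)
  truth_base <- cbind(base_sim$truth,
                      type = rep("none", n_base))
  truth_ty <- if (n_ty > 0)
    data.frame(probe_id = ids_ty, class = "transition", period_hr = tau_ty,
               phase_hr = phi_ty, rel_amplitude = A, type = ty,
               stringsAsFactors = FALSE)
  else truth_base[0, ]
  truth <- rbind(truth_base, truth_ty)
  list(ld = TimeCourseMatrix(ld_arr, ids, regime = "LD",
                             sampling_interval_hr = spec$sampling_interval_hr),
       dd = TimeCourseMatrix(dd_arr, ids, regime = "DD",
                             sampling_interval_hr = spec$sampling_interval_hr),
       truth = truth)
}

#' Simulate promoter sequences with planted consensus elements
#'
#' Uniform-random A/C/G/T background with exact motif instances planted at
#' known upstream positions and strands. The 3' end of each sequence is the
#' transcription start site; positions are negative 1-based distances
#' upstream of the TSS (the motif's 5'-most base).
#'
#' @param n number of sequences.
#' @param length sequence length in bp.
#' @param planted data.frame with columns `seq` (index in `1..n`), `motif`
#'   (name), `pattern` (exact ACGT string planted), `pos` (negative upstream
#'   coordinate of the 5'-most base), `strand` (`"+"` or `"-"`).
#' @param seed integer seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and `truth`,
#'   a data.frame `gene_id`, `motif`, `start`, `strand`, `match`.
#' @export
simulate_promoters <- function(n, length, planted = NULL, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("gene_%03d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), "")
  truth <- data.frame(gene_id = character(0), motif = character(0),
                      start = integer(0), strand = character(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted) > 0) {
    for (k in seq_len(nrow(planted))) {
      p <- planted[k, ]
      w <- nchar(p$pattern)
      if (w > length) stop("motif longer than sequence")
      stopifnot(p$pos < 0, -p$pos <= length, -p$pos >= w)
      a <- length + p$pos + 1          # subject index of the 5'-most base
      ins <- if (p$strand == "+") p$pattern else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(p$pattern)))
      substr(seqs[p$seq], a, a + w - 1) <- ins
      # palindromic plants are canonically reported on the plus strand
      strand_out <- if (identical(ins, p$pattern) &&
                        identical(as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(p$pattern))), p$pattern))
        "+" else p$strand
      truth <- rbind(truth, data.frame(
        gene_id = ids[p$seq], motif = p$motif, start = as.integer(p$pos),
        strand = strand_out, match = p$pattern, stringsAsFactors = FALSE))
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  list(sequences = out, truth = truth)
}
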
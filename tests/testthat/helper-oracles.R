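# Independent oracles kept deliberately naive: each re-derives the quantity
# a different way than the package implementation.

# O(n^2) trigonometric-sum DFT magnitude for component k of series x
naive_dft_mag <- function(x, k) {
  n <- length(x)
  j <- seq_len(n) - 1
  re <- sum(x * cos(2 * pi * k * j / n))
  im <- -sum(x * sin(2 * pi * k * j / n))
  sqrt(re^2 + im^2)
}

# explicit double-loop zero-padded 'same' sliding correlation
naive_sliding_corr <- function(y, taps) {
  L <- length(taps); half <- (L - 1) %/% 2
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(L)) {
      idx <- i + j - 1 - half
      if (idx >= 1 && idx <= n) acc <- acc + y[idx] * taps[j]
    }
    out[i] <- acc
  }
  out
}

# all permutations of a vector (n <= 9)
permn <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- vector("list", 0)
  for (i in seq_along(v))
    for (p in permn(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# exact one-sided Kendall/JT p-value by exhaustive enumeration of all
# orderings of x against a fixed reference
exact_kendall_p <- function(x, ref) {
  n <- length(x)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sgn <- function(v) sign(v[pairs[, 2]] - v[pairs[, 1]])
  sr <- sgn(ref)
  s_obs <- sum(sgn(x) * sr)
  svals <- vapply(permn(seq_len(n)), function(p) sum(sgn(x[p]) * sr), 0)
  mean(svals >= s_obs)
}

# full gamut + mean-centering front end, then the naive correlation,
# mirroring the pulse_score contract independently
naive_pulse_cmax <- function(signal, taps) {
  rng <- range(signal)
  if (diff(rng) == 0) return(0)
  y <- (signal - rng[1]) / diff(rng)
  y <- y - mean(y)
  max(naive_sliding_corr(y, taps))
}

# study grid shorthand
study_times <- function(n = 13) 4 * (seq_len(n) - 1)

cos_profile <- function(baseline, A, tau, phase_hr, t_hr) {
  baseline * (1 + A * cos(2 * pi * (t_hr - phase_hr) / tau))
}
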
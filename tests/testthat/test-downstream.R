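test_that("phase distribution: hand counts, right-closed bins, lowest-q rule", {
  calls <- data.frame(
    probe_id = c("a1", "a2", "b1"),
    statistic = c(0.01, 0.02, 0.03),
    peak_phase_hr = c(2, 2, 14), stringsAsFactors = FALSE)
  pd <- phase_distribution(calls, bin_width_hr = 4)
  expect_equal(pd$percent[pd$bin_end_hr == 4], 200 / 3, tolerance = 1e-9)
  expect_equal(pd$percent[pd$bin_end_hr == 16], 100 / 3, tolerance = 1e-9)
  expect_equal(sum(pd$percent), 100)
  # gene with two probes contributes only its lowest-q phase
  calls2 <- data.frame(probe_id = c("p1", "p2"),
                       statistic = c(0.01, 0.04),
                       peak_phase_hr = c(4, 16), stringsAsFactors = FALSE)
  gm <- data.frame(probe_id = c("p1", "p2"), gene_id = c("g", "g"))
  pd2 <- phase_distribution(calls2, gene_map = gm, bin_width_hr = 4)
  expect_equal(pd2$n[pd2$bin_end_hr == 4], 1)
  expect_equal(sum(pd2$n), 1)
  # right-closed: phase exactly on an edge falls in the ending bin,
  # phase 0 wraps into the (21, 24] bin
  calls3 <- data.frame(probe_id = c("x", "y"), statistic = c(0.01, 0.01),
                       peak_phase_hr = c(3, 0), stringsAsFactors = FALSE)
  pd3 <- phase_distribution(calls3, bin_width_hr = 3)
  expect_equal(pd3$n[pd3$bin_end_hr == 3], 1)
  expect_equal(pd3$n[pd3$bin_end_hr == 24], 1)
})

test_that("uniform phases give an approximately flat distribution", {
  set.seed(31)
  calls <- data.frame(probe_id = sprintf("p%d", 1:600),
                      statistic = runif(600),
                      peak_phase_hr = runif(600, 0, 24),
                      stringsAsFactors = FALSE)
  pd <- phase_distribution(calls, bin_width_hr = 3)
  expect_gt(chisq.test(pd$n)$p.value, 0.01)
})

test_that("peak/nadir amplitude honors the 8-16 h interval rule", {
  t13 <- study_times()
  x <- cos_profile(100, 0.5, 24, 0, t13)   # peak t=0, trough t=12
  am <- peak_nadir_amplitude(x, t13)
  expect_true(am$valid)
  expect_equal(am$interval_hr, 12)
  expect_equal(am$ratio, 150 / 50)          # (B+A)/(B-A)
  spik <- rep(100, 13); spik[5] <- 300; spik[6] <- 20
  am2 <- peak_nadir_amplitude(spik, t13)   # peak/trough 4 h apart
  expect_false(am2$valid)
  expect_equal(am2$ratio, 15)               # still reported, flagged
  z <- rep(1, 13); z[2] <- 0; z[4] <- 5
  expect_false(peak_nadir_amplitude(z, t13)$valid)  # zero nadir
})

test_that("LD/DD fold change arithmetic and type III vs I ordering", {
  arr_ld <- array(200, c(1, 13, 2)); arr_dd <- array(50, c(1, 13, 2))
  f <- ld_dd_fold(TimeCourseMatrix(arr_ld, "p", regime = "LD"),
                  TimeCourseMatrix(arr_dd, "p", regime = "DD"))
  expect_equal(f$table$fold, 4)
  expect_equal(f$table$direction, "LD-high")
  same <- TimeCourseMatrix(arr_ld, "p", regime = "LD")
  f2 <- ld_dd_fold(same, TimeCourseMatrix(arr_ld, "p", regime = "DD"))
  expect_equal(f2$table$fold, 1)
  expect_equal(f2$fraction_over_2fold, 0)
  # type III probes show larger LD-high folds than type I at matched params
  pair <- simulate_ld_dd_pair(simulation_spec(n_type_I = 10,
                                              n_type_III = 10,
                                              sigma = 0.05, seed = 32))
  ff <- ld_dd_fold(pair$ld, pair$dd)$table
  tI <- ff$fold[grepl("^typeI_", ff$probe_id)]
  tIII <- ff$fold[grepl("^typeIII_", ff$probe_id)]
  expect_gt(mean(tIII), mean(tI))
})

test_that("classifier recovers generator labels on noiseless pairs", {
  spec <- simulation_spec(n_type_I = 5, n_type_II = 5, n_type_III = 5,
                          n_arrhythmic = 3, sigma = 0, period_hr = 24,
                          seed = 33)
  pair <- simulate_ld_dd_pair(spec)
  jl <- run_jtk(pair$ld); jd <- run_jtk(pair$dd)
  got <- vapply(seq_along(pair$ld$probe_ids), function(i) {
    pid <- pair$ld$probe_ids[i]
    classify_ld_dd_type(
      apply(pair$ld$intensities[i, , , drop = FALSE], 2, mean),
      apply(pair$dd$intensities[i, , , drop = FALSE], 2, mean),
      rhythmic_ld = jl$statistic[i] < 0.05 && jl$in_window[i],
      rhythmic_dd = jd$statistic[i] < 0.05 && jd$in_window[i],
      t_hr = time_hours(pair$ld))
  }, "")
  want <- ifelse(pair$truth$type == "none", "other", pair$truth$type)
  expect_identical(got, want)
})

test_that("clustering normalizes, merges duplicates at zero and is order-stable", {
  t13 <- study_times()
  arr <- array(0, c(4, 13, 1))
  arr[1, , 1] <- cos_profile(100, 0.5, 24, 0, t13)
  arr[2, , 1] <- cos_profile(80, 0.4, 24, 0, t13)    # in phase with 1
  arr[3, , 1] <- cos_profile(100, 0.5, 24, 12, t13)  # antiphase
  arr[4, , 1] <- arr[1, , 1]                          # duplicate of 1
  tc <- TimeCourseMatrix(arr, c("a", "b", "anti", "dup"), regime = "LD")
  hc <- hierarchical_cluster(tc)
  m <- hc$tree$merge
  h <- hc$tree$height
  lab <- hc$tree$labels
  # identical profiles merge first at distance ~0
  first <- sort(lab[-m[1, ]])
  expect_identical(first, c("a", "dup"))
  expect_lt(h[1], 1e-10)
  # normalized rows: mean 0, unit sum of squares
  expect_equal(unname(rowSums(hc$matrix)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(rowSums(hc$matrix^2)), rep(1, 4), tolerance = 1e-9)
  # permutation invariance of topology (same merge heights)
  tc2 <- subset_probes(tc, c("anti", "dup", "a", "b"))
  hc2 <- hierarchical_cluster(tc2)
  expect_equal(sort(hc2$tree$height), sort(h), tolerance = 1e-12)
})

test_that("planted 3-cluster structure is recovered exactly at zero noise", {
  t13 <- study_times()
  phases <- rep(c(0, 8, 16), each = 4)
  arr <- array(0, c(12, 13, 1))
  for (i in 1:12)
    arr[i, , 1] <- cos_profile(100 + i, 0.4, 24, phases[i], t13)
  tc <- TimeCourseMatrix(arr, sprintf("g%02d", 1:12), regime = "LD")
  hc <- hierarchical_cluster(tc)
  k3 <- cutree(hc$tree, k = 3)
  expect_equal(length(unique(paste(k3, phases))), 3)  # pure clusters
})

test_that("z-scored profiles have mean 0 / sd 1 and are affine invariant", {
  spec <- simulation_spec(n_sinusoidal = 5, sigma = 0.1, seed = 34)
  tc <- simulate_matrix(spec, "LD")$tc
  z <- zscore_profiles(tc)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  tc2 <- tc
  tc2$intensities <- 2.5 * tc$intensities + 40
  expect_equal(zscore_profiles(tc2), z, tolerance = 1e-9)
  const <- TimeCourseMatrix(array(7, c(1, 13, 1)), "c")
  expect_message(zc <- zscore_profiles(const), "constant")
  expect_equal(unname(zc[1, ]), rep(0, 13))
})
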
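# minimal call tables in run_jtk shape
mk_species_calls <- function(ids, q, phase) {
  data.frame(probe_id = ids, detector = "JTK", statistic = q,
             p = q, period_hr = 24, peak_phase_hr = phase,
             amplitude = 1, tau = 1, in_window = TRUE,
             stringsAsFactors = FALSE)
}

test_that("highest-identity rhythmic homologue is chosen", {
  a <- mk_species_calls("gA", 0.01, 4)
  b <- mk_species_calls(c("b1", "b2"), c(0.5, 0.01), c(NA, 10))
  hom <- data.frame(gene_a = c("gA", "gA"), gene_b = c("b1", "b2"),
                    pct_identity = c(90, 80), stringsAsFactors = FALSE)
  pr <- match_rhythmic_orthologs(a, b, hom)
  expect_equal(pr$gene_b, "b2")      # b1 has higher identity but arrhythmic
  expect_true(pr$rhythmic_b)
  expect_equal(pr$phase_b, 10)
  # single arrhythmic homologue: kept with rhythmic_b = FALSE, no phase
  b2 <- mk_species_calls("b1", 0.5, NA)
  pr2 <- match_rhythmic_orthologs(a, b2, hom[1, ])
  expect_false(pr2$rhythmic_b)
  expect_equal(pr2$gene_b, "b1")
  expect_true(is.na(pr2$phase_b))
  # absent from the homology table
  pr3 <- match_rhythmic_orthologs(a, b, hom[0, ])
  expect_true(is.na(pr3$gene_b))
})

test_that("probes collapse to the lowest q per gene and ties break lexically", {
  a <- mk_species_calls(c("p1", "p2"), c(0.04, 0.001), c(2, 8))
  gm <- data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
  b <- mk_species_calls(c("b1", "b2"), c(0.01, 0.01), c(1, 2))
  hom <- data.frame(gene_a = c("gA", "gA"), gene_b = c("b2", "b1"),
                    pct_identity = c(88, 88))
  pr <- match_rhythmic_orthologs(a, b, hom, gene_map_a = gm)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$phase_a, 8)        # lowest-q probe
  expect_equal(pr$gene_b, "b1")      # lexical tie-break at equal identity
})

test_that("category table counts and totals satisfy the column inequalities", {
  pairs <- data.frame(
    gene_a = c("g1", "g2", "g3"),
    gene_b = c("h1", "h2", NA),
    pct_identity = c(90, 85, NA),
    rhythmic_a = TRUE,
    rhythmic_b = c(TRUE, FALSE, FALSE),
    phase_a = c(1, 2, 3), phase_b = c(5, NA, NA),
    stringsAsFactors = FALSE)
  tab <- category_table(pairs, c(g1 = "Metabolism", g2 = "Metabolism",
                                 g3 = "Metabolism"))
  row <- tab[tab$category == "Metabolism", ]
  expect_equal(unlist(row[, 2:4], use.names = FALSE), c(3, 2, 1))
  tot <- tab[tab$category == "Totals", ]
  expect_equal(tot$rhythmic_a, sum(tab$rhythmic_a[tab$category != "Totals"]))
  expect_true(all(tab$rhythmic_homolog <= tab$with_homolog))
  expect_true(all(tab$with_homolog <= tab$rhythmic_a))
  # empty category map -> Unknown
  tab2 <- category_table(pairs)
  expect_true("Unknown" %in% tab2$category)
})

test_that("phase concordance folds differences and detects antiphase", {
  pairs <- data.frame(gene_a = c("g1", "g2"), gene_b = c("h1", "h2"),
                      pct_identity = 90, rhythmic_a = TRUE,
                      rhythmic_b = TRUE,
                      phase_a = c(12, 3), phase_b = c(0, 3),
                      stringsAsFactors = FALSE)
  pc <- phase_concordance(pairs)
  expect_equal(sort(pc$differences$delta_hr), c(0, 12))
  # no doubly rhythmic pairs -> empty summary
  pairs$rhythmic_b <- FALSE
  expect_true(is.na(phase_concordance(pairs)$circular_mean_hr))
})

test_that("phase differences are equivariant under a common shift", {
  pairs <- data.frame(gene_a = sprintf("g%d", 1:5),
                      gene_b = sprintf("h%d", 1:5),
                      pct_identity = 90, rhythmic_a = TRUE,
                      rhythmic_b = TRUE,
                      phase_a = c(0, 5, 10, 15, 20),
                      phase_b = c(2, 7, 12, 17, 22),
                      stringsAsFactors = FALSE)
  base <- phase_concordance(pairs)$circular_mean_hr
  pairs$phase_b <- (pairs$phase_b + 6) %% 24
  expect_equal(phase_concordance(pairs)$circular_mean_hr,
               ((base + 6 + 12) %% 24) - 12)
})

test_that("simulated two-species shared rhythmic fraction is recovered", {
  # species A: 40 rhythmic genes; half their orthologs rhythmic in B
  set.seed(41)
  nA <- 40
  idsA <- sprintf("a%02d", 1:nA)
  idsB <- sprintf("b%02d", 1:nA)
  shared <- rep(c(TRUE, FALSE), each = nA / 2)
  a <- mk_species_calls(idsA, rep(0.01, nA), runif(nA, 0, 24))
  b <- mk_species_calls(idsB, ifelse(shared, 0.01, 0.8),
                        ifelse(shared, runif(nA, 0, 24), NA))
  hom <- data.frame(gene_a = idsA, gene_b = idsB,
                    pct_identity = runif(nA, 50, 100))
  pr <- match_rhythmic_orthologs(a, b, hom)
  expect_equal(mean(pr$rhythmic_b), 0.5)
  # antiphase gene family: circular mean difference ~ 12 h
  ph_a <- runif(20, 0, 24)
  a2 <- mk_species_calls(sprintf("x%d", 1:20), 0.01, ph_a)
  b2 <- mk_species_calls(sprintf("y%d", 1:20), 0.01,
                         (ph_a + 12 + rnorm(20, 0, 0.5)) %% 24)
  hom2 <- data.frame(gene_a = sprintf("x%d", 1:20),
                     gene_b = sprintf("y%d", 1:20), pct_identity = 80)
  pc <- phase_concordance(match_rhythmic_orthologs(a2, b2, hom2))
  expect_lt(min(abs(pc$circular_mean_hr - 12),
                abs(pc$circular_mean_hr + 12)), 1)
  expect_gt(pc$concentration, 0.9)
})
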
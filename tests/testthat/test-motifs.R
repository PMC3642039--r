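test_that("pattern subsumption: canonical E box also hits the generic pattern", {
  motifs <- motif_definitions()
  seq_ <- paste0(strrep("T", 30), "CACGTG", strrep("T", 30))
  hits <- scan_region(seq_, motifs, gene_id = "g")
  ebox <- hits[hits$motif %in% c("E_box_generic", "E_box_canonical"), ]
  expect_setequal(ebox$motif, c("E_box_generic", "E_box_canonical"))
  # one hit per motif at the same position; palindrome reported once
  expect_equal(nrow(ebox), 2)
  expect_equal(unique(ebox$start), -36)
  expect_true(all(ebox$strand == "+"))
})

test_that("reverse-strand instances are found with strand '-'", {
  motifs <- data.frame(name = "CRE", pattern = "TGACGTCA")
  # plant the reverse complement of CRE (palindrome? TGACGTCA rc = TGACGTCA)
  # use a non-palindromic pattern instead
  motifs <- data.frame(name = "W_box", pattern = "TTGACY")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTGACC")))
  seq_ <- paste0(strrep("A", 20), rc, strrep("A", 20))
  hits <- scan_region(seq_, motifs, gene_id = "g")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$match, "TTGACC")
  expect_equal(hits$start, -(20 + 6))
})

test_that("N in the subject never matches", {
  motifs <- data.frame(name = "E_box_generic", pattern = "CANNTG")
  hits <- scan_region(paste0("AAAA", "CANATG", "AAAA"), motifs)
  expect_equal(nrow(hits), 0)
  hits2 <- scan_region(paste0("AAAA", "CATATG", "AAAA"), motifs)
  expect_equal(nrow(hits2), 1)
})

test_that("empty sequences and too-long patterns yield empty hit lists", {
  motifs <- motif_definitions()
  expect_equal(nrow(scan_region("", motifs)), 0)
  expect_equal(nrow(scan_region("ACG", motifs)), 0)
})

test_that("scanner round-trips planted motifs exactly (modulo background)", {
  motifs <- motif_definitions()
  planted <- data.frame(
    seq = c(1, 1, 2, 3),
    motif = c("E_box_canonical", "CRE", "W_box", "PDP1"),
    pattern = c("CACGTG", "TGACGTCA", "TTGACT", "TTATGTAA"),
    pos = c(-1200, -400, -777, -1500),
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  prom <- simulate_promoters(4, 2000, planted, seed = 91)
  hits <- scan_promoters(prom$sequences, motifs)
  # every planted instance is recovered with position and strand
  for (k in seq_len(nrow(prom$truth))) {
    tr <- prom$truth[k, ]
    found <- hits[hits$gene_id == tr$gene_id & hits$motif == tr$motif &
                    hits$start == tr$start & hits$strand == tr$strand, ]
    expect_equal(nrow(found), 1)
  }
  # chance background hits verified by a brute-force IUPAC scan oracle
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
             H = "ACT", V = "ACG", N = "ACGT")
  brute_hits <- function(seq_, pattern) {
    L <- nchar(seq_); w <- nchar(pattern)
    ok <- logical(0)
    pat <- strsplit(pattern, "")[[1]]
    starts <- integer(0)
    for (a in seq_len(L - w + 1)) {
      sub <- strsplit(substr(seq_, a, a + w - 1), "")[[1]]
      if (all(mapply(function(s, p) grepl(s, iupac[[p]], fixed = TRUE),
                     sub, pat)))
        starts <- c(starts, a)
    }
    starts
  }
  seq1 <- as.character(prom$sequences[[1]])
  for (m in c("E_box_generic", "W_box")) {
    pat <- motifs$pattern[motifs$name == m]
    plus_oracle <- brute_hits(seq1, pat) - nchar(seq1) - 1
    got <- sort(hits$start[hits$gene_id == "gene_001" & hits$motif == m &
                             hits$strand == "+"])
    expect_equal(got, sort(plus_oracle))
  }
})

test_that("strand-flip symmetry: scanning the reverse complement mirrors hits", {
  motifs <- motif_definitions()
  set.seed(92)
  seq_ <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  h_fwd <- scan_region(seq_, motifs)
  h_rev <- scan_region(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_))), motifs)
  expect_equal(nrow(h_fwd), nrow(h_rev))
  per_motif <- table(h_fwd$motif)
  expect_equal(as.vector(table(h_rev$motif)[names(per_motif)]),
               as.vector(per_motif))
})

test_that("window tabulation nests 1 kb inside 5 kb and records region size", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    motif = c("CRE", "CRE", "CRE"),
    start = c(-800, -3000, -500),
    strand = "+", match = "TGACGTCA", stringsAsFactors = FALSE)
  tab <- tabulate_hits(hits, c(g1 = 5000L, g2 = 1700L))
  g1 <- tab[tab$gene_id == "g1", ]
  expect_equal(g1$n_1000bp, 1)   # -800 in both windows
  expect_equal(g1$n_5000bp, 2)   # -3000 only in 5 kb
  g2 <- tab[tab$gene_id == "g2", ]
  expect_equal(g2$region_bp, 1700L)
  expect_true(all(tab$n_1000bp <= tab$n_5000bp))
})
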
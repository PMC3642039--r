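#' Default consensus-element definitions
#'
#' Loads the editable motif table shipped in
#' `inst/extdata/motifs.tsv`: E boxes (generic CANNTG and canonical
#' CACGTG), W box, CRE, Per-repeat (PERR), Tim-E-box-like repeat (TER) and
#' PDP1 binding-site patterns as IUPAC degenerate strings. W box (TTGACY)
#' and CRE (TGACGTCA) are literature consensus; the PERR, TER and PDP1
#' defaults are placeholders that users should review against their own
#' source before drawing biological conclusions — patterns are data, not
#' code.
#'
#' @param path optional path to an alternative two-column TSV
#'   (`name`, `pattern`).
#' @return data.frame with columns `name` and `pattern`.
#' @export
motif_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motifs.tsv", package = "rhythmscan",
                        mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("name", "pattern") %in% names(df)))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", df$pattern)
  if (any(bad))
    stop("non-IUPAC pattern(s): ", paste(df$pattern[bad], collapse = ", "))
  df
}

# is a pattern its own reverse complement under IUPAC expansion?
.is_palindrome <- function(pattern) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  identical(rc, pattern)
}

# matchPattern with pattern-side IUPAC expansion; subject literal.
# Returns start positions. Hits touching an N in the subject are dropped.
.scan_one_strand <- function(pattern, subject) {
  hits <- Biostrings::matchPattern(pattern, subject,
                                   fixed = "subject")
  st <- BiocGenerics::start(hits)
  if (length(st)) {
    w <- nchar(pattern)
    keep <- !vapply(st, function(a)
      grepl("N", as.character(Biostrings::subseq(subject, a, a + w - 1)),
            fixed = TRUE), TRUE)
    st <- st[keep]
  }
  st
}

#' Scan one upstream region for consensus elements
#'
#' Both strands are scanned with IUPAC-degenerate exact matching; the TSS
#' is the 3' end of the supplied sequence and positions are reported as
#' negative 1-based distances upstream of the TSS (the match's 5'-most base
#' on the plus strand). Overlapping matches are all reported; matches of a
#' palindromic pattern are reported once per position (plus strand). An
#' `N` in the subject never matches.
#'
#' @param sequence a [Biostrings::DNAString] or character string (upstream
#'   region, 5' to 3', TSS at the right end).
#' @param motifs data.frame (`name`, `pattern`), e.g.
#'   [motif_definitions()].
#' @param gene_id identifier attached to the hits.
#' @return data.frame: `gene_id`, `motif`, `start` (negative), `strand`,
#'   `match` (pattern-strand sequence).
#' @export
scan_region <- function(sequence, motifs = motif_definitions(),
                        gene_id = "gene") {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  L <- length(sequence)
  empty <- data.frame(gene_id = character(0), motif = character(0),
                      start = integer(0), strand = character(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (L == 0) return(empty)
  rcseq <- Biostrings::reverseComplement(sequence)
  out <- list(empty)
  for (k in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[k]
    w <- nchar(pat)
    if (w > L) next
    fwd <- .scan_one_strand(pat, sequence)
    if (length(fwd))
      out[[length(out) + 1]] <- data.frame(
        gene_id = gene_id, motif = motifs$name[k],
        start = as.integer(fwd - L - 1), strand = "+",
        match = vapply(fwd, function(a)
          as.character(Biostrings::subseq(sequence, a, a + w - 1)), ""),
        stringsAsFactors = FALSE)
    if (!.is_palindrome(pat)) {
      rev_ <- .scan_one_strand(pat, rcseq)
      if (length(rev_)) {
        # rc position a..a+w-1 maps to plus-strand L-a-w+2..L-a+1
        plus_start <- L - (rev_ + w - 1) + 1
        out[[length(out) + 1]] <- data.frame(
          gene_id = gene_id, motif = motifs$name[k],
          start = as.integer(plus_start - L - 1), strand = "-",
          match = vapply(rev_, function(a)
            as.character(Biostrings::subseq(rcseq, a, a + w - 1)), ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$motif, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Scan a set of upstream regions
#'
#' @param sequences a named [Biostrings::DNAStringSet] of upstream regions.
#' @param motifs data.frame (`name`, `pattern`).
#' @return combined hit data.frame as in [scan_region()].
#' @export
scan_promoters <- function(sequences, motifs = motif_definitions()) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("gene_%03d", seq_along(sequences))
  hits <- lapply(seq_along(sequences), function(i)
    scan_region(sequences[[i]], motifs, gene_id = ids[i]))
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}

#' Tabulate motif hits in 1 kb and 5 kb upstream windows
#'
#' Counts hits per gene per motif whose 5'-most base lies within each
#' window of the TSS (half-open `(0, W]` on the upstream distance), and
#' records the available region length so truncated upstream regions
#' (e.g. < 1.8 kb before the next coding region) are interpretable.
#'
#' @param hits data.frame from [scan_region()]/[scan_promoters()].
#' @param region_lengths named integer vector: available upstream bp per
#'   gene.
#' @param windows upstream window sizes in bp (default `c(1000, 5000)`).
#' @return data.frame: `gene_id`, `region_bp`, `motif`, one
#'   `n_<window>bp` count column per window.
#' @export
tabulate_hits <- function(hits, region_lengths,
                          windows = c(1000, 5000)) {
  genes <- names(region_lengths)
  motifs <- sort(unique(hits$motif))
  grid <- expand.grid(gene_id = genes, motif = motifs,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$gene_id, grid$motif), ]
  grid$region_bp <- as.integer(region_lengths[grid$gene_id])
  for (w in windows) {
    cnt <- mapply(function(g, m)
      sum(hits$gene_id == g & hits$motif == m & -hits$start <= w),
      grid$gene_id, grid$motif)
    grid[[sprintf("n_%dbp", w)]] <- as.integer(cnt)
  }
  rownames(grid) <- NULL
  grid[, c("gene_id", "region_bp", "motif",
           sprintf("n_%dbp", windows))]
}
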
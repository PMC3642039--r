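#' Match rhythmic genes to their best rhythmic orthologs
#'
#' For every rhythmic species-A gene (q below `q_max`, probes collapsed to
#' the lowest q), the species-B homolog with the highest percent identity
#' that is itself rhythmic is selected; when none of its homologs are
#' rhythmic the top-identity homolog is kept with `rhythmic_b = FALSE`.
#' Genes absent from the homology table are recorded with `gene_b = NA`.
#' Percent-identity ties break lexicographically by `gene_b`.
#'
#' @param calls_a,calls_b per-species rank-test outputs (as [run_jtk()],
#'   must carry `probe_id`, `statistic`, `peak_phase_hr`, `in_window`);
#'   both produced with the same configuration family.
#' @param homology data.frame with columns `gene_a`, `gene_b`,
#'   `pct_identity` (in (0, 100]).
#' @param gene_map_a,gene_map_b optional data.frames (`probe_id`,
#'   `gene_id`); `NULL` takes probe ids as gene ids.
#' @param q_max rhythmicity cutoff for both species (default 0.05).
#' @return data.frame of `OrthologPair` rows: `gene_a`, `gene_b`,
#'   `pct_identity`, `rhythmic_a`, `rhythmic_b`, `phase_a`, `phase_b`
#'   (phases only when the corresponding species calls the gene rhythmic).
#' @export
match_rhythmic_orthologs <- function(calls_a, calls_b, homology,
                                     gene_map_a = NULL, gene_map_b = NULL,
                                     q_max = 0.05) {
  collapse <- function(calls, gene_map) {
    g <- if (is.null(gene_map)) calls$probe_id else
      gene_map$gene_id[match(calls$probe_id, gene_map$probe_id)]
    calls$gene_id <- g
    calls <- calls[order(calls$statistic), ]
    calls[!duplicated(calls$gene_id), ]
  }
  a <- collapse(calls_a, gene_map_a)
  b <- collapse(calls_b, gene_map_b)
  a_rhy <- a[a$statistic < q_max & a$in_window, ]
  b_rhythmic <- b$gene_id[b$statistic < q_max & b$in_window]
  rows <- vector("list", nrow(a_rhy))
  for (i in seq_len(nrow(a_rhy))) {
    ga <- a_rhy$gene_id[i]
    hom <- homology[homology$gene_a == ga, ]
    hom <- hom[order(-hom$pct_identity, hom$gene_b), ]
    if (nrow(hom) == 0) {
      gb <- NA_character_; pid <- NA_real_; rb <- FALSE
    } else {
      rhy_hom <- hom[hom$gene_b %in% b_rhythmic, ]
      if (nrow(rhy_hom) > 0) {
        gb <- rhy_hom$gene_b[1]; pid <- rhy_hom$pct_identity[1]; rb <- TRUE
      } else {
        gb <- hom$gene_b[1]; pid <- hom$pct_identity[1]; rb <- FALSE
      }
    }
    rows[[i]] <- data.frame(
      gene_a = ga, gene_b = gb, pct_identity = pid,
      rhythmic_a = TRUE, rhythmic_b = rb,
      phase_a = a_rhy$peak_phase_hr[i],
      phase_b = if (rb) b$peak_phase_hr[match(gb, b$gene_id)] else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               pct_identity = numeric(0), rhythmic_a = logical(0),
               rhythmic_b = logical(0), phase_a = numeric(0),
               phase_b = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Category count table for a two-species rhythm comparison
#'
#' Per functional category: the number of rhythmic species-A genes, how
#' many of those have a homolog, and how many of the chosen homologs are
#' themselves rhythmic, plus a totals row. Uncategorized genes fall into
#' `"Unknown"`. Column inequalities (rhythmic-homolog <= homolog <=
#' rhythmic-A) hold per row by construction.
#'
#' @param pairs output of [match_rhythmic_orthologs()].
#' @param categories named character vector or data.frame (`gene_id`,
#'   `category`) mapping species-A genes to categories.
#' @return data.frame: `category`, `rhythmic_a`, `with_homolog`,
#'   `rhythmic_homolog`; last row is `Totals`.
#' @export
category_table <- function(pairs, categories = NULL) {
  cat_of <- function(g) {
    if (is.null(categories)) return(rep("Unknown", length(g)))
    v <- if (is.data.frame(categories))
      categories$category[match(g, categories$gene_id)]
    else unname(categories[g])
    ifelse(is.na(v), "Unknown", v)
  }
  pairs$category <- cat_of(pairs$gene_a)
  cats <- sort(unique(pairs$category))
  rows <- lapply(cats, function(cc) {
    p <- pairs[pairs$category == cc, ]
    data.frame(category = cc, rhythmic_a = nrow(p),
               with_homolog = sum(!is.na(p$gene_b)),
               rhythmic_homolog = sum(p$rhythmic_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    category = "Totals", rhythmic_a = sum(out$rhythmic_a),
    with_homolog = sum(out$with_homolog),
    rhythmic_homolog = sum(out$rhythmic_homolog)))
  rownames(out) <- NULL
  out
}

#' Circular phase concordance between doubly rhythmic ortholog pairs
#'
#' Per pair, the circular phase difference `(phase_b - phase_a) mod 24`
#' folded to `(-12, 12]`; the summary is the circular mean difference and
#' the mean resultant length (concentration, 1 = perfectly concordant
#' offsets).
#'
#' @param pairs output of [match_rhythmic_orthologs()]; only rows rhythmic
#'   in both species (phases present) are used.
#' @return list with `differences` (data.frame `gene_a`, `gene_b`,
#'   `delta_hr`), `circular_mean_hr` (folded to `(-12, 12]`) and
#'   `concentration`; empty summary (`NA` mean) when no doubly rhythmic
#'   pairs exist.
#' @export
phase_concordance <- function(pairs) {
  p <- pairs[pairs$rhythmic_a & pairs$rhythmic_b &
               !is.na(pairs$phase_a) & !is.na(pairs$phase_b), ]
  fold <- function(d) {
    d <- d %% 24
    ifelse(d > 12, d - 24, d)
  }
  if (nrow(p) == 0)
    return(list(differences = data.frame(gene_a = character(0),
                                         gene_b = character(0),
                                         delta_hr = numeric(0)),
                circular_mean_hr = NA_real_, concentration = NA_real_))
  delta <- fold(p$phase_b - p$phase_a)
  ang <- delta * 2 * pi / 24
  mean_ang <- atan2(mean(sin(ang)), mean(cos(ang)))
  list(differences = data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
                                delta_hr = delta,
                                stringsAsFactors = FALSE),
       circular_mean_hr = fold(mean_ang * 24 / (2 * pi)),
       concentration = sqrt(mean(sin(ang))^2 + mean(cos(ang))^2))
}
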
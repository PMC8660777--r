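# Seed network construction (motif x chromatin x window intersection) and
# degree normalization.

#' Build the bipartite TF-to-gene seed network
#'
#' Each transcription factor's motif locations are optionally pruned to
#' those falling in open chromatin (>= 1 bp overlap with any peak); the
#' surviving motifs are then intersected with the gene regulatory windows,
#' and an edge TF -> gene is created whenever a motif overlaps any window
#' of the gene. The edge weight is the maximum motif score across all
#' instances hitting the gene's windows (1 when scores are left at the BED
#' default, giving a binary seed). Omitting `open_chromatin` yields the
#' epigenetically naive seed. The result is dense over the declared TF and
#' gene universes: factors or genes with no surviving motif keep all-zero
#' rows/columns so message passing sees the full bipartite graph.
#'
#' @param motif_sets named list, one `GRanges` of motif locations per TF.
#' @param regulatory_regions `GRanges` of gene windows labeled by gene id
#'   (see [buildRegulatoryRegions()]).
#' @param open_chromatin optional `GRanges` of accessible regions; `NULL`
#'   for the naive seed.
#' @param tf_universe,gene_universe character vectors defining the network
#'   axes; must cover `names(motif_sets)` and the window labels.
#' @param unit_scores if `TRUE` (default) every surviving motif location is
#'   given a score of one before edges are weighted, so the seed is binary;
#'   set `FALSE` to propagate BED scores via the max rule.
#' @return a binary (or max-score-weighted) [BipartiteNetwork-class].
#' @export
buildSeedNetwork <- function(motif_sets, regulatory_regions,
                             open_chromatin = NULL,
                             tf_universe = names(motif_sets),
                             gene_universe = NULL,
                             unit_scores = TRUE) {
  if (!length(regulatory_regions)) {
    stop("empty regulatory regions", call. = FALSE)
  }
  region_genes <- S4Vectors::mcols(regulatory_regions)$name
  if (is.null(gene_universe)) gene_universe <- sort(unique(region_genes))
  if (!all(region_genes %in% gene_universe)) {
    stop("gene_universe does not cover all regulatory-region labels",
         call. = FALSE)
  }
  missing_tf <- setdiff(names(motif_sets), tf_universe)
  if (length(missing_tf)) {
    stop("motif set TF(s) absent from tf_universe: ",
         paste(missing_tf, collapse = ", "), call. = FALSE)
  }
  w <- matrix(0, length(tf_universe), length(gene_universe),
              dimnames = list(tf_universe, gene_universe))
  for (tf in names(motif_sets)) {
    motifs <- motif_sets[[tf]]
    if (!is.null(open_chromatin)) {
      motifs <- intersectKeepA(motifs, open_chromatin)
    }
    if (!length(motifs)) next
    score <- if (unit_scores) rep(1, length(motifs)) else
      S4Vectors::mcols(motifs)$score
    hits <- GenomicRanges::findOverlaps(motifs, regulatory_regions,
                                        ignore.strand = TRUE)
    if (!length(hits)) next
    g <- region_genes[S4Vectors::subjectHits(hits)]
    sc <- score[S4Vectors::queryHits(hits)]
    best <- tapply(sc, g, max)
    w[tf, names(best)] <- as.numeric(best)
  }
  BipartiteNetwork(w, binary = all(w %in% c(0, 1)),
                   metadata = if (is.null(open_chromatin))
                     "naive seed (motif x windows)" else
                       "seed (motif x open chromatin x windows)")
}

#' Average node degrees of a bipartite network
#'
#' For seed matrix A, the TF degree is the row mean `k_i = mean_j(A_ij)`
#' and the gene degree the column mean `k_j = mean_i(A_ij)`; for a binary
#' seed both lie in \[0, 1\].
#'
#' @param net a [BipartiteNetwork-class].
#' @return list with numeric vectors `tf_degrees` and `gene_degrees`.
#' @export
averageDegrees <- function(net) {
  w <- weightMatrix(net)
  list(tf_degrees = rowMeans(w), gene_degrees = colMeans(w))
}

#' Degree-normalize a seed network
#'
#' Rescales each edge by the joint magnitude of its endpoints' average
#' degrees: `A*_ij = A_ij * sqrt(k_i^2 + k_j^2)` with `k_i`, `k_j` the
#' TF row mean and gene column mean of A. This emphasizes edges attached
#' to high-degree (chromatin-rich) factors and genes and counter-balances
#' the Z-score transform applied at the start of message passing. Zero
#' entries stay exactly zero.
#'
#' @param net seed [BipartiteNetwork-class] with finite non-negative
#'   weights.
#' @return degree-normalized [BipartiteNetwork-class] (non-binary).
#' @export
degreeNormalize <- function(net) {
  w <- weightMatrix(net)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("seed weights must be finite and non-negative", call. = FALSE)
  }
  k_tf <- rowMeans(w)
  k_g <- colMeans(w)
  scale <- sqrt(outer(k_tf^2, k_g^2, `+`))
  BipartiteNetwork(w * scale, binary = FALSE,
                   metadata = "degree-normalized seed")
}
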
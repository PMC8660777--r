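# Detection of hidden interactions: refined edges with no supporting seed
# evidence whose message-passing weight is significantly high on the
# Z-score scale.

#' Upper-tail normal probabilities for edge weights
#'
#' Message-passing edge weights are distributed approximately like
#' Z-scores, so each weight is converted to the probability of a standard
#' normal draw at least that large (high weight = small p). A weight of
#' 4.64 maps to p = 1.74e-6.
#'
#' @param weights finite numeric vector of edge weights.
#' @return vector of upper-tail probabilities.
#' @export
edgePvalues <- function(weights) {
  if (any(!is.finite(weights))) {
    stop("non-finite edge weights", call. = FALSE)
  }
  stats::pnorm(weights, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment `q_(i) = min_{k >= i} (m p_(k) / k)`,
#' clipped at 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Select significant hidden edges
#'
#' Restricts the refined network to edges whose seed weight is exactly
#' zero (no in-window accessible motif), converts their weights to
#' upper-tail normal probabilities, applies Benjamini-Hochberg over
#' exactly that candidate set (m = number of absent-in-seed edges), and
#' selects edges with q below the FDR threshold. Reports the attained
#' weight cutoff (smallest selected weight) and a per-gene tally of
#' selected edges, ordered by descending weight (ties broken by TF then
#' gene axis order).
#'
#' @param spider_net refined weighted [BipartiteNetwork-class].
#' @param seed_net seed [BipartiteNetwork-class] on identical axes.
#' @param fdr false discovery rate threshold in (0, 1); default 0.05.
#' @return list of class `HiddenEdgeReport`: `edges` (data.frame tf, gene,
#'   weight, p, q), `fdr_threshold`, `weight_cutoff_attained`,
#'   `gene_tally`, `n_candidates`.
#' @export
selectHiddenEdges <- function(spider_net, seed_net, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  .checkSameAxes(spider_net, seed_net)
  w <- weightMatrix(spider_net)
  s <- weightMatrix(seed_net)
  cand <- which(s == 0)
  if (!length(cand)) {
    stop("no absent-in-seed candidate edges", call. = FALSE)
  }
  p <- edgePvalues(w[cand])
  q <- bhAdjust(p)
  sel <- cand[q < fdr]
  psel <- p[q < fdr]; qsel <- q[q < fdr]
  idx <- arrayInd(sel, dim(w))
  o <- order(-w[sel], idx[, 1], idx[, 2])
  edges <- data.frame(tf = rownames(w)[idx[o, 1]],
                      gene = colnames(w)[idx[o, 2]],
                      weight = w[sel][o],
                      p = psel[o], q = qsel[o],
                      stringsAsFactors = FALSE)
  tally <- if (nrow(edges)) sort(table(edges$gene), decreasing = TRUE)
           else table(character(0))
  structure(list(edges = edges,
                 fdr_threshold = fdr,
                 weight_cutoff_attained = if (nrow(edges))
                   min(edges$weight) else NA_real_,
                 gene_tally = tally,
                 n_candidates = length(cand)),
            class = "HiddenEdgeReport")
}

#' Top-weight edges split by seed motif evidence
#'
#' For a subset of transcription factors (typically the ChIP-assayed
#' ones), returns the `k` highest-weight refined edges that have seed
#' (motif) evidence and the `k` highest-weight edges that do not. Ordering
#' is by descending weight, ties broken by TF then gene axis order; when
#' fewer than `k` candidates exist all are returned with a warning.
#'
#' @param spider_net refined weighted [BipartiteNetwork-class].
#' @param seed_net seed [BipartiteNetwork-class] on identical axes.
#' @param tfs TF subset to restrict to (default: all).
#' @param k number of edges per list.
#' @return list with data.frames `with_motif` and `without_motif`
#'   (columns tf, gene, weight).
#' @export
rankTopEdges <- function(spider_net, seed_net, tfs = tfNames(spider_net),
                         k = 3L) {
  stopifnot(k >= 1)
  .checkSameAxes(spider_net, seed_net)
  w <- weightMatrix(spider_net)[tfs, , drop = FALSE]
  s <- weightMatrix(seed_net)[tfs, , drop = FALSE]
  if (sum(s != 0) < k || sum(s == 0) < k) {
    warning("fewer than k candidate edges; returning all", call. = FALSE)
  }
  topk <- function(mask) {
    idx <- which(mask)
    ai <- arrayInd(idx, dim(w))
    o <- order(-w[idx], ai[, 1], ai[, 2])
    o <- o[seq_len(min(k, length(idx)))]
    data.frame(tf = rownames(w)[ai[o, 1]],
               gene = colnames(w)[ai[o, 2]],
               weight = w[idx][o], stringsAsFactors = FALSE)
  }
  list(with_motif = topk(s != 0), without_motif = topk(s == 0))
}

#' Write a hidden-edge report as TSV
#'
#' @param report a `HiddenEdgeReport` from [selectHiddenEdges()].
#' @param path output TSV for the edge table.
#' @param tally_path optional output TSV for the per-gene tally.
#' @return `path`, invisibly.
#' @export
writeHiddenEdgeReport <- function(report, path, tally_path = NULL) {
  utils::write.table(report$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tally_path)) {
    utils::write.table(
      data.frame(gene = names(report$gene_tally),
                 n_edges = as.integer(report$gene_tally)),
      tally_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
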
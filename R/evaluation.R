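# Benchmarking predicted networks against ChIP-seq-derived gold standards:
# gold construction, global and per-TF AUC/AUPR, differential-network
# evaluation, thresholding and confusion rates.

#' Build a binary gold-standard network from ChIP-seq peaks
#'
#' Replicate peak sets for each factor are merged into one composite set
#' ([mergeOverlapping()]), then intersected with the gene regulatory
#' windows exactly as in seed construction: edge = 1 iff at least one
#' merged peak overlaps at least one window of the gene. Factors with an
#' empty peak set are kept as all-zero rows with a warning.
#'
#' @param chip_sets named list, one `GRanges` of ChIP peaks per assayed TF.
#' @param regulatory_regions `GRanges` of gene windows labeled by gene id.
#' @param gene_universe character vector of gene names (the prediction's
#'   gene axis).
#' @return a binary [BipartiteNetwork-class] over assayed TFs x genes.
#' @export
buildGoldStandard <- function(chip_sets, regulatory_regions,
                              gene_universe = NULL) {
  merged <- lapply(chip_sets, mergeOverlapping)
  empty <- names(merged)[lengths(merged) == 0]
  if (length(empty)) {
    warning("TF(s) with empty ChIP peak set kept as all-zero rows: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  net <- buildSeedNetwork(merged, regulatory_regions,
                          open_chromatin = NULL,
                          tf_universe = names(chip_sets),
                          gene_universe = gene_universe,
                          unit_scores = TRUE)
  BipartiteNetwork(weightMatrix(net), binary = TRUE,
                   metadata = "ChIP-derived gold standard")
}

#' Flatten the common-TF subnetwork into score/label vectors
#'
#' Restricts prediction and gold standard to their shared transcription
#' factors (gene axes must be identical) and flattens all possible edges of
#' that subnetwork into aligned score and label vectors; `n` is
#' `|common TFs| x N_G` (e.g. 19 TFs x 27,090 genes = 514,710 edges).
#'
#' @param pred weighted [BipartiteNetwork-class] of predictions.
#' @param gold binary [BipartiteNetwork-class] gold standard.
#' @return list with `scores`, `labels` (0/1), `n`, `common_tfs`.
#' @export
restrictToCommon <- function(pred, gold) {
  if (!identical(geneNames(pred), geneNames(gold))) {
    stop("prediction and gold standard gene axes differ", call. = FALSE)
  }
  common <- intersect(tfNames(pred), tfNames(gold))
  if (!length(common)) {
    stop("no transcription factors shared between prediction and gold standard",
         call. = FALSE)
  }
  s <- weightMatrix(pred)[common, , drop = FALSE]
  l <- weightMatrix(gold)[common, , drop = FALSE]
  list(scores = as.vector(s), labels = as.vector(l),
       n = length(common) * ncol(s), common_tfs = common)
}

.checkTwoClasses <- function(labels) {
  if (all(labels == 1)) {
    stop("degenerate labels: all positive", call. = FALSE)
  }
  if (all(labels == 0)) {
    stop("degenerate labels: all negative", call. = FALSE)
  }
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Computed with the midrank convention, so it equals the probability that
#' a random positive outscores a random negative plus half the tie
#' probability. Invariant under strictly monotone score transforms; binary
#' or three-valued scores give piecewise-linear ROC chords.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector (both classes required).
#' @return AUC in \[0, 1\].
#' @export
aucROC <- function(scores, labels) {
  labels <- as.numeric(labels)
  .checkTwoClasses(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One point per distinct score threshold (plus the (0,0) origin), with
#' ties collapsed, so scores taking k distinct values give a curve of k
#' linear segments.
#'
#' @inheritParams aucROC
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.numeric(labels)
  .checkTwoClasses(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(labels == 0)),
             tpr = c(0, tp[keep] / sum(labels == 1)))
}

#' Precision-recall curve points
#'
#' @inheritParams aucROC
#' @return data.frame with columns `recall`, `precision` (ties collapsed).
#' @export
prCurve <- function(scores, labels) {
  labels <- as.numeric(labels)
  .checkTwoClasses(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l)
  prec <- tp / seq_along(tp)
  rec <- tp / sum(l)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(recall = rec[keep], precision = prec[keep])
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration over the ranked predictions. Binary scores make
#' the curve degenerate, so when `jitter_sigma > 0` seeded Gaussian noise
#' of that standard deviation (default 0.05) is added to the scores before
#' ranking; with `jitter_sigma = 0` the computation is deterministic. The
#' baseline for uninformative scores is the positive fraction.
#'
#' @inheritParams aucROC
#' @param jitter_sigma standard deviation of the Gaussian jitter; 0
#'   disables.
#' @param seed integer RNG seed for the jitter (the global RNG state is
#'   left untouched).
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels, jitter_sigma = 0, seed = 1L) {
  labels <- as.numeric(labels)
  .checkTwoClasses(labels)
  stopifnot(jitter_sigma >= 0)
  if (jitter_sigma > 0) {
    scores <- scores + .withLocalSeed(seed, stats::rnorm(length(scores),
                                                         0, jitter_sigma))
  }
  pr <- prCurve(scores, labels)
  r <- c(0, pr$recall)
  # precision at recall 0 taken as the first observed precision
  p <- c(pr$precision[1], pr$precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

# Evaluate an expression under a temporary RNG seed, restoring state.
.withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Global evaluation of a predicted network against a gold standard
#'
#' @inheritParams restrictToCommon
#' @param jitter_sigma,seed passed to [aupr()] (jitter is only meaningful
#'   for binary predictions).
#' @return list of class `EvaluationResult`: `auc`, `aupr`,
#'   `n_edges_evaluated`, `positive_fraction`, `roc_points`, `pr_points`,
#'   `scope`.
#' @export
evaluateNetwork <- function(pred, gold, jitter_sigma = 0, seed = 1L) {
  rc <- restrictToCommon(pred, gold)
  # jitter affects only the PR computation (AUC is rank-based with midrank
  # tie handling and needs no tie-breaking noise)
  structure(list(
    auc = aucROC(rc$scores, rc$labels),
    aupr = aupr(rc$scores, rc$labels, jitter_sigma = jitter_sigma,
                seed = seed),
    n_edges_evaluated = rc$n,
    positive_fraction = mean(rc$labels),
    roc_points = rocCurve(rc$scores, rc$labels),
    pr_points = prCurve(rc$scores, rc$labels),
    scope = "global"
  ), class = "EvaluationResult")
}

#' Per-transcription-factor evaluation
#'
#' Scores each common TF's row independently. Rows whose gold labels are
#' single-class are flagged not-evaluable (`NA` metrics) and excluded from
#' any summary statistics.
#'
#' @inheritParams restrictToCommon
#' @param jitter_sigma,seed passed to [aupr()] per row.
#' @return data.frame with one row per common TF: `tf`, `auc`, `aupr`,
#'   `n_positives`, `evaluable`.
#' @export
perTFEvaluation <- function(pred, gold, jitter_sigma = 0, seed = 1L) {
  common <- intersect(tfNames(pred), tfNames(gold))
  if (!length(common)) stop("no common TFs", call. = FALSE)
  s <- weightMatrix(pred)[common, , drop = FALSE]
  l <- weightMatrix(gold)[common, , drop = FALSE]
  res <- lapply(seq_along(common), function(i) {
    li <- l[i, ]
    if (all(li == 0) || all(li == 1)) {
      return(data.frame(tf = common[i], auc = NA_real_, aupr = NA_real_,
                        n_positives = sum(li), evaluable = FALSE))
    }
    data.frame(tf = common[i],
               auc = aucROC(s[i, ], li),
               aupr = aupr(s[i, ], li, jitter_sigma = jitter_sigma,
                           seed = seed + i),
               n_positives = sum(li),
               evaluable = TRUE)
  })
  do.call(rbind, res)
}

#' Difference of two networks over identical axes
#'
#' Entrywise `A - B`. For binary inputs the result takes values in
#' \{-1, 0, +1\}: edges specific to context A (+1), specific to B (-1),
#' or identical in both (0).
#'
#' @param netA,netB [BipartiteNetwork-class] objects with identical axes.
#' @return a [BipartiteNetwork-class] holding the differential weights.
#' @export
differentialNetwork <- function(netA, netB) {
  .checkSameAxes(netA, netB)
  BipartiteNetwork(weightMatrix(netA) - weightMatrix(netB),
                   binary = FALSE, metadata = "differential network (A - B)")
}

#' Evaluate a differential prediction against a differential gold standard
#'
#' Edges where the gold differential is +1 form the positive class and -1
#' the negative class; edges identical in both contexts (0) are excluded.
#' The predicted differential weight is the score. Restrict both inputs to
#' TFs assayed in both contexts before calling.
#'
#' @param pred_diff,gold_diff differential [BipartiteNetwork-class]
#'   objects ([differentialNetwork()]) on identical axes; `gold_diff` must
#'   hold values in \{-1, 0, 1\}.
#' @return list of class `EvaluationResult` (AUC, ROC points, counts).
#' @export
evaluateDifferential <- function(pred_diff, gold_diff) {
  .checkSameAxes(pred_diff, gold_diff)
  g <- as.vector(weightMatrix(gold_diff))
  if (!all(g %in% c(-1, 0, 1))) {
    stop("gold differential must take values in {-1, 0, +1}", call. = FALSE)
  }
  keep <- g != 0
  if (!any(keep)) {
    stop("gold differential has no context-specific (+1/-1) edges",
         call. = FALSE)
  }
  s <- as.vector(weightMatrix(pred_diff))[keep]
  l <- as.numeric(g[keep] == 1)
  .checkTwoClasses(l)
  structure(list(auc = aucROC(s, l),
                 aupr = aupr(s, l),
                 n_edges_evaluated = sum(keep),
                 positive_fraction = mean(l),
                 roc_points = rocCurve(s, l),
                 pr_points = prCurve(s, l),
                 scope = "differential"),
            class = "EvaluationResult")
}

#' Threshold a weighted network into a binary one
#'
#' Density rule: keep the top `ceiling(density * N_TF * N_G)` weights,
#' ties broken by descending weight then row-major axis order (TF index,
#' then gene index). Cutoff rule: keep weights strictly greater than
#' `cutoff`.
#'
#' @param net weighted [BipartiteNetwork-class].
#' @param density fraction of edges to keep, in (0, 1\].
#' @param cutoff absolute weight cutoff (used when `density` is `NULL`).
#' @return binary [BipartiteNetwork-class].
#' @export
thresholdNetwork <- function(net, density = NULL, cutoff = NULL) {
  w <- weightMatrix(net)
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  if (!is.null(density)) {
    stopifnot(density > 0, density <= 1)
    k <- ceiling(density * length(w))
    idx <- arrayInd(seq_along(w), dim(w))
    o <- order(-as.vector(w), idx[, 1], idx[, 2])
    out[o[seq_len(k)]] <- 1
  } else if (!is.null(cutoff)) {
    stopifnot(is.finite(cutoff) || is.infinite(cutoff))
    out[w > cutoff] <- 1
  } else {
    stop("provide either density or cutoff", call. = FALSE)
  }
  BipartiteNetwork(out, binary = TRUE, metadata = "thresholded network")
}

#' Confusion rates of a binary prediction against a gold standard
#'
#' Over the common-TF subnetwork: TPR = TP/(TP+FN), TNR = TN/(TN+FP),
#' FPR = FP/(FP+TN), FNR = FN/(FN+TP). Rates whose denominator is zero
#' (gold standard lacking one class) are reported as `NA`.
#'
#' @param pred_binary binary [BipartiteNetwork-class] prediction.
#' @param gold binary [BipartiteNetwork-class] gold standard.
#' @return list of class `ConfusionRates` with `tpr`, `tnr`, `fpr`, `fnr`
#'   and the four counts.
#' @export
confusionRates <- function(pred_binary, gold) {
  if (!isBinary(pred_binary) || !isBinary(gold)) {
    stop("both networks must be binary", call. = FALSE)
  }
  rc <- restrictToCommon(pred_binary, gold)
  p <- rc$scores; g <- rc$labels
  tp <- sum(p == 1 & g == 1); fn <- sum(p == 0 & g == 1)
  tn <- sum(p == 0 & g == 0); fp <- sum(p == 1 & g == 0)
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  structure(list(tpr = rate(tp, fn), tnr = rate(tn, fp),
                 fpr = rate(fp, tn), fnr = rate(fn, tp),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "ConfusionRates")
}
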
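test_that("gold standards are built from merged composite peaks", {
  windows <- intervalSet("chr1", 4000, 6000, name = "G1")
  chip <- list(TFA = intervalSet("chr1", 4900, 5100, name = "TFA"))
  g <- buildGoldStandard(chip, windows, gene_universe = "G1")
  expect_true(isBinary(g))
  expect_equal(weightMatrix(g)["TFA", "G1"], 1)

  # replicate peaks merge into one composite and count once
  chip <- list(TFA = intervalSet(c("chr1", "chr1"), c(4900, 5050),
                                 c(5100, 5300), name = "TFA"))
  g <- buildGoldStandard(chip, windows, gene_universe = "G1")
  expect_equal(weightMatrix(g)["TFA", "G1"], 1)

  # empty peak set kept as an all-zero row with warning
  chip <- list(TFA = intervalSet("chr1", 4900, 5100),
               TFB = intervalSet(character(0), integer(0), integer(0)))
  expect_warning(g <- buildGoldStandard(chip, windows, "G1"), "TFB")
  expect_equal(unname(weightMatrix(g)["TFB", "G1"]), 0)
})

test_that("gold construction matches the triple-loop oracle", {
  set.seed(31)
  genes <- sprintf("G%02d", 1:20)
  ann <- geneAnnotation(genes, "chr1", seq(3000, by = 3000, length.out = 20))
  windows <- buildRegulatoryRegions(ann)
  tfs <- c("TFA", "TFB", "TFC")
  chip_dfs <- lapply(tfs, function(tf) {
    s <- sample.int(70000, 25)
    data.frame(chrom = "chr1", start = s, end = s + 300, name = tf,
               stringsAsFactors = FALSE)
  })
  names(chip_dfs) <- tfs
  got <- weightMatrix(buildGoldStandard(lapply(chip_dfs, dfToIntervals),
                                        windows, genes))
  want <- bruteSeed(chip_dfs, intervalsToDf(windows), NULL, tfs, genes)
  expect_equal(got, want)
})

test_that("restrictToCommon flattens the common-TF subnetwork", {
  pred <- makeNet(matrix(rnorm(4 * 6), 4, 6))
  gold <- BipartiteNetwork(matrix(rbinom(18, 1, 0.4), 3, 6,
                                  dimnames = list(sprintf("TF%02d", 1:3),
                                                  geneNames(pred))),
                           binary = TRUE)
  rc <- restrictToCommon(pred, gold)
  expect_equal(rc$n, 3 * 6)
  expect_length(rc$scores, 18)
  expect_length(rc$labels, 18)

  disjoint <- BipartiteNetwork(matrix(1, 1, 6,
                                      dimnames = list("ZZZ",
                                                      geneNames(pred))),
                               binary = TRUE)
  expect_error(restrictToCommon(pred, disjoint), "shared")
})

test_that("AUC equals the Mann-Whitney pair enumeration", {
  expect_equal(aucROC(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(aucROC(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucROC(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(aucROC(1:3, c(1, 1, 1)), "all positive")
  expect_error(aucROC(1:3, c(0, 0, 0)), "all negative")
  set.seed(32)
  for (rep in 1:5) {
    s <- sample(seq(0, 1, 0.1), 60, replace = TRUE)  # force ties
    l <- rbinom(60, 1, 0.4)
    if (all(l == l[1])) next
    expect_equal(aucROC(s, l), bruteAUC(s, l), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(aucROC(exp(3 * s), l), aucROC(s, l), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  s <- rnorm(200)
  l <- rbinom(200, 1, 0.3)
  expect_equal(aucROC(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("AUPR reaches its closed-form anchors", {
  expect_equal(aupr(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1.0)
  # random scores sit near the positive-fraction baseline
  set.seed(34)
  s <- runif(1e4)
  l <- rbinom(1e4, 1, 0.2)
  expect_equal(aupr(s, l), mean(l), tolerance = 0.03)
  # deterministic without jitter; reproducible and stable with jitter on
  # binary scores that only partly agree with the labels (the jitter must
  # break ties within each score block for AUPR to be well-defined)
  sc <- rbinom(1e5, 1, 0.15) * 1.0
  flip <- as.logical(rbinom(1e5, 1, 0.2))
  lab <- ifelse(flip, 1 - sc, sc)
  a1 <- aupr(sc, lab, jitter_sigma = 0.05, seed = 1)
  a2 <- aupr(sc, lab, jitter_sigma = 0.05, seed = 1)
  a3 <- aupr(sc, lab, jitter_sigma = 0.05, seed = 2)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_lt(abs(a1 - a3), 0.01)
})

test_that("per-TF evaluation applies the row-wise metrics independently", {
  set.seed(35)
  w <- matrix(rnorm(3 * 30), 3, 30)
  g <- matrix(rbinom(90, 1, 0.3), 3, 30)
  g[3, ] <- 0  # not evaluable
  pred <- makeNet(w)
  gold <- BipartiteNetwork(g, tfs = tfNames(pred), genes = geneNames(pred),
                           binary = TRUE)
  res <- perTFEvaluation(pred, gold)
  expect_equal(nrow(res), 3)
  expect_false(res$evaluable[3])
  expect_true(is.na(res$auc[3]))
  for (i in 1:2) {
    expect_equal(res$auc[i], aucROC(w[i, ], g[i, ]))
  }
  # identical score rows, different gold rows: independent AUCs
  w2 <- rbind(w[1, ], w[1, ])
  g2 <- rbind(g[1, ], g[2, ])
  pred2 <- makeNet(w2); gold2 <- BipartiteNetwork(
    g2, tfs = tfNames(pred2), genes = geneNames(pred2), binary = TRUE)
  res2 <- perTFEvaluation(pred2, gold2)
  expect_equal(res2$auc[1], res$auc[1])
  expect_equal(res2$auc[2], aucROC(w[1, ], g[2, ]))
})

test_that("differential networks subtract entrywise with {-1,0,1} classes", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  A <- makeNet(a, binary = TRUE)
  B <- BipartiteNetwork(b, tfs = tfNames(A), genes = geneNames(A),
                        binary = TRUE)
  d <- weightMatrix(differentialNetwork(A, B))
  expect_equal(as.vector(d), c(1, 0, 0, -1))
  expect_equal(as.vector(weightMatrix(differentialNetwork(A, A))),
               rep(0, 4))
  expect_error(differentialNetwork(A, makeNet(matrix(0, 3, 2))), "axes")
})

test_that("differential evaluation scores +1 vs -1 and drops identical edges", {
  set.seed(36)
  g <- matrix(sample(c(-1, 0, 1), 40, replace = TRUE), 4, 10)
  gold <- makeNet(g)
  perfect <- makeNet(g)
  expect_equal(evaluateDifferential(perfect, gold)$auc, 1.0)
  flat <- makeNet(matrix(0, 4, 10))
  expect_equal(evaluateDifferential(flat, gold)$auc, 0.5)
  expect_equal(evaluateDifferential(flat, gold)$n_edges_evaluated,
               sum(g != 0))
  expect_error(evaluateDifferential(flat, makeNet(matrix(0, 4, 10))),
               "no context-specific")

  # antisymmetry: swapping contexts leaves the AUC unchanged
  p <- makeNet(matrix(rnorm(40), 4, 10))
  pneg <- makeNet(-weightMatrix(p))
  gneg <- makeNet(-g)
  expect_equal(evaluateDifferential(p, gold)$auc,
               evaluateDifferential(pneg, gneg)$auc, tolerance = 1e-12)

  # three-valued scores trace a three-segment ROC; AUC matches pair counts
  s3 <- makeNet(matrix(sample(c(-1, 0, 1), 40, replace = TRUE), 4, 10))
  ev <- evaluateDifferential(s3, gold)
  expect_equal(nrow(ev$roc_points) - 1, 3)
  keep <- as.vector(g) != 0
  expect_equal(ev$auc, bruteAUC(as.vector(weightMatrix(s3))[keep],
                                as.numeric(as.vector(g)[keep] == 1)),
               tolerance = 1e-12)
})

test_that("thresholding keeps the declared density or cutoff", {
  set.seed(37)
  w <- matrix(rnorm(20), 4, 5)
  net <- makeNet(w)
  expect_equal(sum(weightMatrix(thresholdNetwork(net, density = 1))), 20)
  expect_equal(sum(weightMatrix(thresholdNetwork(net, cutoff = Inf))), 0)
  th <- thresholdNetwork(net, density = 0.2)
  expect_equal(sum(weightMatrix(th)), 4)
  # sort-and-slice oracle
  kept <- which(weightMatrix(th) == 1)
  expect_setequal(kept, order(-as.vector(w))[1:4])
})

test_that("confusion rates satisfy their complement identities", {
  set.seed(38)
  g <- matrix(rbinom(12, 1, 0.5), 3, 4)
  gold <- makeNet(g, binary = TRUE)
  same <- makeNet(g, binary = TRUE)
  cr <- confusionRates(same, gold)
  expect_equal(c(cr$tpr, cr$tnr, cr$fpr, cr$fnr), c(1, 1, 0, 0))
  comp <- makeNet(1 - g, binary = TRUE)
  cr <- confusionRates(comp, gold)
  expect_equal(c(cr$tpr, cr$tnr, cr$fpr, cr$fnr), c(0, 0, 1, 1))
  p <- matrix(rbinom(12, 1, 0.5), 3, 4)
  cr <- confusionRates(makeNet(p, binary = TRUE), gold)
  # four-counter oracle
  expect_equal(cr$tp, sum(p == 1 & g == 1))
  expect_equal(cr$fn, sum(p == 0 & g == 1))
  expect_equal(cr$tpr + cr$fnr, 1, tolerance = 1e-12)
  expect_equal(cr$tnr + cr$fpr, 1, tolerance = 1e-12)
})

test_that("global evaluation reports n = |common TFs| x N_G and both curves", {
  set.seed(39)
  pred <- makeNet(matrix(rnorm(5 * 40), 5, 40))
  gold <- BipartiteNetwork(matrix(rbinom(200, 1, 0.2), 5, 40,
                                  dimnames = list(tfNames(pred),
                                                  geneNames(pred))),
                           binary = TRUE)
  ev <- evaluateNetwork(pred, gold)
  expect_equal(ev$n_edges_evaluated, 200)
  expect_true(ev$positive_fraction > 0 && ev$positive_fraction < 1)
  expect_true(all(c("fpr", "tpr") %in% names(ev$roc_points)))
  expect_true(all(c("recall", "precision") %in% names(ev$pr_points)))
})
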
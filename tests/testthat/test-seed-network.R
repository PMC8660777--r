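test_that("seed edges require motif, chromatin, and window to align", {
  windows <- intervalSet("chr1", 4000, 6000, name = "G1")
  motifs <- list(TFA = intervalSet("chr1", 4500, 4510, name = "TFA"))
  open_near <- intervalSet("chr1", 4400, 4700)
  open_far <- intervalSet("chr1", 7000, 7500)

  w <- weightMatrix(buildSeedNetwork(motifs, windows, open_near,
                                     tf_universe = "TFA",
                                     gene_universe = "G1"))
  expect_equal(w["TFA", "G1"], 1)

  w <- weightMatrix(buildSeedNetwork(motifs, windows, open_far,
                                     tf_universe = "TFA",
                                     gene_universe = "G1"))
  expect_equal(w["TFA", "G1"], 0)
  # the naive seed ignores chromatin
  w <- weightMatrix(buildSeedNetwork(motifs, windows, NULL,
                                     tf_universe = "TFA",
                                     gene_universe = "G1"))
  expect_equal(w["TFA", "G1"], 1)
})

test_that("edge weight is the max motif score when scores are propagated", {
  windows <- intervalSet("chr1", 4000, 6000, name = "G1")
  motifs <- list(TFA = intervalSet(c("chr1", "chr1"), c(4500, 5000),
                                   c(4510, 5010), name = "TFA",
                                   score = c(2.0, 3.5)))
  w <- weightMatrix(buildSeedNetwork(motifs, windows, NULL,
                                     tf_universe = "TFA",
                                     gene_universe = "G1",
                                     unit_scores = FALSE))
  expect_equal(w["TFA", "G1"], 3.5)
  # default pipeline resets scores to one
  w <- weightMatrix(buildSeedNetwork(motifs, windows, NULL,
                                     tf_universe = "TFA",
                                     gene_universe = "G1"))
  expect_equal(w["TFA", "G1"], 1)
})

test_that("seed construction validates its inputs", {
  windows <- intervalSet("chr1", 4000, 6000, name = "G1")
  motifs <- list(TFA = intervalSet("chr1", 4500, 4510))
  expect_error(buildSeedNetwork(motifs, windows[integer(0)]),
               "empty regulatory regions")
  expect_error(buildSeedNetwork(motifs, windows, tf_universe = "TFB",
                                gene_universe = "G1"),
               "absent from tf_universe")
  expect_error(buildSeedNetwork(motifs, windows, gene_universe = "G2"),
               "does not cover")
})

test_that("seed network matches the triple-loop oracle on random instances", {
  set.seed(41)
  n_tf <- 10; n_gene <- 30
  tfs <- sprintf("TF%02d", 1:n_tf)
  genes <- sprintf("G%03d", 1:n_gene)
  tss <- seq(3000, by = 3000, length.out = n_gene)
  ann <- geneAnnotation(genes, "chr1", tss)
  windows <- buildRegulatoryRegions(ann)
  windows_df <- intervalsToDf(windows)
  motif_dfs <- lapply(tfs, function(tf) {
    n <- 40
    s <- sample.int(max(tss) + 2000, n)
    data.frame(chrom = "chr1", start = s, end = s + 10, name = tf,
               stringsAsFactors = FALSE)
  })
  names(motif_dfs) <- tfs
  cs <- sample.int(max(tss) + 2000, 60)
  chromatin_df <- data.frame(chrom = "chr1", start = cs, end = cs + 150,
                             name = "", stringsAsFactors = FALSE)

  got <- weightMatrix(buildSeedNetwork(lapply(motif_dfs, dfToIntervals),
                                       windows,
                                       dfToIntervals(chromatin_df),
                                       tf_universe = tfs,
                                       gene_universe = genes))
  want <- bruteSeed(motif_dfs, windows_df, chromatin_df, tfs, genes)
  expect_equal(got, want)

  naive <- weightMatrix(buildSeedNetwork(lapply(motif_dfs, dfToIntervals),
                                         windows, NULL,
                                         tf_universe = tfs,
                                         gene_universe = genes))
  expect_equal(naive, bruteSeed(motif_dfs, windows_df, NULL, tfs, genes))
  # chromatin filtering only removes support
  expect_true(all(got <= naive))
})

test_that("degree normalization follows the row/column mean formula", {
  A <- matrix(c(1, 1, 0, 1), 2, 2,
              dimnames = list(c("TFA", "TFB"), c("g1", "g2")))
  # k_TF = (0.5, 1), k_Gene = (1, 0.5)
  got <- weightMatrix(degreeNormalize(BipartiteNetwork(A)))
  want <- matrix(c(sqrt(1.25), sqrt(2), 0, sqrt(1.25)), 2, 2,
                 dimnames = dimnames(A))
  expect_equal(got, want, tolerance = 1e-12)

  # all-zero and all-one closed forms
  z <- matrix(0, 3, 4, dimnames = list(letters[1:3], letters[4:7]))
  expect_equal(weightMatrix(degreeNormalize(BipartiteNetwork(z))), z)
  o <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[6:10]))
  expect_equal(weightMatrix(degreeNormalize(BipartiteNetwork(o))),
               sqrt(2) * o)
})

test_that("degree normalization preserves support and is edge-monotone", {
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(rbinom(6 * 10, 1, 0.4), 6, 10,
                dimnames = list(sprintf("t%d", 1:6), sprintf("g%d", 1:10)))
    As <- weightMatrix(degreeNormalize(BipartiteNetwork(A)))
    expect_identical(As == 0, A == 0)
    # add an edge to TF 1: its existing edges never decrease
    zero <- which(A[1, ] == 0)
    if (length(zero)) {
      A2 <- A
      A2[1, zero[1]] <- 1
      As2 <- weightMatrix(degreeNormalize(BipartiteNetwork(A2)))
      on_edges <- A[1, ] == 1
      expect_true(all(As2[1, on_edges] >= As[1, on_edges]))
    }
  }
})

test_that("degrees from a binary seed are averages in [0, 1]", {
  set.seed(9)
  A <- matrix(rbinom(40, 1, 0.5), 5, 8,
              dimnames = list(sprintf("t%d", 1:5), sprintf("g%d", 1:8)))
  d <- averageDegrees(BipartiteNetwork(A, binary = TRUE))
  expect_true(all(d$tf_degrees >= 0 & d$tf_degrees <= 1))
  expect_true(all(d$gene_degrees >= 0 & d$gene_degrees <= 1))
  expect_equal(d$tf_degrees, rowMeans(A))
})

test_that("binary validity is enforced on BipartiteNetwork", {
  w <- matrix(c(0.3, 1), 1, 2, dimnames = list("t", c("g1", "g2")))
  expect_error(BipartiteNetwork(w, binary = TRUE), "outside")
  expect_error(BipartiteNetwork(matrix(1, 2, 2,
                                       dimnames = list(c("a", "a"),
                                                       c("g1", "g2")))),
               "duplicate")
})

test_that("network TSV formats round-trip exactly", {
  set.seed(11)
  w <- matrix(rnorm(12), 3, 4,
              dimnames = list(sprintf("t%d", 1:3), sprintf("g%d", 1:4)))
  net <- BipartiteNetwork(w)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(net, f)
  expect_equal(weightMatrix(readEdgeList(f)), w)
  writeDenseNetwork(net, f)
  expect_equal(weightMatrix(readDenseNetwork(f)), w)
})
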
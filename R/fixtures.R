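# Seeded synthetic input bundles: a toy chromosome with regularly spaced
# TSSs, a planted module-structured TF-to-gene truth network, motif BEDs
# with controlled dropout (recoverable hidden edges), open-chromatin peaks
# covering a tunable fraction of motif sites, and ChIP peaks derived from
# the truth with noise. Everything the pipeline consumes can be generated
# here, deterministically, from a single integer seed.

#' Specify a synthetic fixture
#'
#' The planted structure is modular: transcription factors are assigned
#' round-robin to `n_modules` co-regulatory modules and every factor in a
#' module targets the same gene set (drawn per module). This shared-target
#' structure is exactly what message passing exploits, so edges whose
#' motif was dropped remain recoverable from the rest of their module.
#'
#' @param n_tfs,n_genes numbers of transcription factors and genes.
#' @param n_modules number of co-regulatory TF modules (`<= n_tfs`).
#' @param target_frac fraction of genes targeted by each module.
#' @param motif_dropout probability that a true edge emits no motif site
#'   (a planted hidden edge).
#' @param chromatin_closed_frac probability that an emitted true-edge
#'   motif site is left outside open chromatin.
#' @param decoy_edge_rate probability that a non-edge gets an in-window
#'   motif in closed chromatin (naive-seed false positives).
#' @param n_decoy_intergenic intergenic decoy motif sites per TF.
#' @param chip_fpr,chip_fnr ChIP peak noise rates relative to the truth.
#' @param window a [regulatoryRegionSpec()].
#' @param gene_spacing bp between consecutive TSSs; must exceed the full
#'   window span so windows never overlap.
#' @param rng_seed integer seed; the bundle is a deterministic function of
#'   the spec.
#' @return list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(n_tfs = 20, n_genes = 200, n_modules = 4,
                        target_frac = 0.25,
                        motif_dropout = 0.2, chromatin_closed_frac = 0.1,
                        decoy_edge_rate = 0.02, n_decoy_intergenic = 5,
                        chip_fpr = 0, chip_fnr = 0,
                        window = regulatoryRegionSpec(),
                        gene_spacing = 5000, rng_seed = 1L) {
  probs <- c(motif_dropout, chromatin_closed_frac, decoy_edge_rate,
             chip_fpr, chip_fnr)
  stopifnot(all(probs >= 0 & probs <= 1), n_modules <= n_tfs,
            n_modules >= 1, target_frac > 0, target_frac <= 1,
            inherits(window, "RegulatoryRegionSpec"))
  span <- if (window$mode == "proximal") 2 * window$proximal_halfwidth
          else 2 * (window$distal_inner + window$distal_width)
  if (gene_spacing <= span) {
    stop("infeasible spec: gene_spacing must exceed the window span (",
         span, " bp) so windows do not overlap", call. = FALSE)
  }
  slot_width <- 50
  slots <- if (window$mode == "proximal") 2 * window$proximal_halfwidth
           else window$distal_width
  if (slots / slot_width < n_tfs) {
    stop("infeasible spec: window too narrow for one motif slot per TF",
         call. = FALSE)
  }
  structure(list(n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 target_frac = target_frac,
                 motif_dropout = motif_dropout,
                 chromatin_closed_frac = chromatin_closed_frac,
                 decoy_edge_rate = decoy_edge_rate,
                 n_decoy_intergenic = as.integer(n_decoy_intergenic),
                 chip_fpr = chip_fpr, chip_fnr = chip_fnr,
                 window = window,
                 gene_spacing = as.numeric(gene_spacing),
                 rng_seed = as.integer(rng_seed)),
            class = "FixtureSpec")
}

# Draw one target-gene set per module.
.drawModuleTargets <- function(spec) {
  n_target <- max(1L, floor(spec$n_genes * spec$target_frac))
  .withLocalSeed(spec$rng_seed, lapply(seq_len(spec$n_modules), function(k)
    sort(sample.int(spec$n_genes, n_target))))
}

# Emission window (where motif slots live) for each gene: the proximal
# window, or the downstream distal window.
.emissionWindowStart <- function(spec, tss) {
  w <- spec$window
  if (w$mode == "proximal") tss - w$proximal_halfwidth
  else tss + w$distal_inner
}

.generateFromModules <- function(spec, module_targets, noise_seed) {
  n_tfs <- spec$n_tfs; n_genes <- spec$n_genes
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  tss <- spec$gene_spacing * seq_len(n_genes)
  genes <- geneAnnotation(gene_ids, "chrS", tss)
  windows <- buildRegulatoryRegions(genes, spec$window)

  module_of <- ((seq_len(n_tfs) - 1L) %% spec$n_modules) + 1L
  truth <- matrix(0, n_tfs, n_genes, dimnames = list(tfs, gene_ids))
  for (i in seq_len(n_tfs)) truth[i, module_targets[[module_of[i]]]] <- 1

  slot_width <- 50
  win_start <- .emissionWindowStart(spec, tss)
  # motif slot for (tf i, gene j): disjoint 50-bp slots indexed by TF, so
  # open-chromatin peaks around one motif can never cover another TF's site
  motif_start <- function(i, j) win_start[j] + (i - 1) * slot_width + 20

  .withLocalSeed(noise_seed, {
    dropped <- matrix(stats::runif(n_tfs * n_genes) < spec$motif_dropout,
                      n_tfs, n_genes)
    closed <- matrix(stats::runif(n_tfs * n_genes) <
                       spec$chromatin_closed_frac, n_tfs, n_genes)
    decoy <- matrix(stats::runif(n_tfs * n_genes) < spec$decoy_edge_rate,
                    n_tfs, n_genes)
    chip_draw <- matrix(stats::runif(n_tfs * n_genes), n_tfs, n_genes)
    intergenic <- lapply(seq_len(n_tfs), function(i)
      sample.int(n_genes, min(spec$n_decoy_intergenic, n_genes)))
  })

  motif_sets <- vector("list", n_tfs); names(motif_sets) <- tfs
  open_start <- numeric(0); open_end <- numeric(0)
  chip_sets <- vector("list", n_tfs); names(chip_sets) <- tfs
  hidden <- list()

  for (i in seq_len(n_tfs)) {
    ms <- numeric(0)
    for (j in seq_len(n_genes)) {
      if (truth[i, j] == 1) {
        if (dropped[i, j]) {
          hidden[[length(hidden) + 1L]] <- c(tfs[i], gene_ids[j])
        } else {
          s <- motif_start(i, j)
          ms <- c(ms, s)
          if (!closed[i, j]) {
            open_start <- c(open_start, s - 20)
            open_end <- c(open_end, s + 30)
          }
        }
      } else if (decoy[i, j]) {
        ms <- c(ms, motif_start(i, j))   # never covered by open chromatin
      }
    }
    # intergenic decoys: midway between a gene's window span and the next TSS
    ig <- tss[intergenic[[i]]] + spec$gene_spacing / 2 + (i - 1) * 15
    ms <- c(ms, ig)
    motif_sets[[i]] <- intervalSet(rep("chrS", length(ms)), ms, ms + 10,
                                   name = tfs[i])
    chip_hit <- (truth[i, ] == 1 & chip_draw[i, ] >= spec$chip_fnr) |
      (truth[i, ] == 0 & chip_draw[i, ] < spec$chip_fpr)
    cj <- which(chip_hit)
    chip_sets[[i]] <- intervalSet(rep("chrS", length(cj)),
                                  .emissionWindowStart(spec, tss[cj]) + 100,
                                  .emissionWindowStart(spec, tss[cj]) + 300,
                                  name = tfs[i])
  }
  open_chromatin <- if (length(open_start))
    mergeOverlapping(intervalSet(rep("chrS", length(open_start)),
                                 open_start, open_end))
  else intervalSet(character(0), integer(0), integer(0))

  hidden_df <- if (length(hidden)) {
    m <- do.call(rbind, hidden)
    data.frame(tf = m[, 1], gene = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(tf = character(0), gene = character(0))

  structure(list(spec = spec,
                 genes = genes,
                 windows = windows,
                 motif_sets = motif_sets,
                 open_chromatin = open_chromatin,
                 chip_sets = chip_sets,
                 truth = BipartiteNetwork(truth, binary = TRUE,
                                          metadata = "planted truth"),
                 hidden_truth_edges = hidden_df),
            class = "FixtureBundle")
}

#' Generate a synthetic fixture bundle
#'
#' @param spec a [fixtureSpec()].
#' @return list of class `FixtureBundle` with elements `genes`, `windows`,
#'   `motif_sets`, `open_chromatin`, `chip_sets`, `truth`
#'   (binary [BipartiteNetwork-class]), `hidden_truth_edges` and `spec`.
#'   Deterministic given `spec$rng_seed`.
#' @export
generateFixture <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .generateFromModules(spec, .drawModuleTargets(spec),
                       noise_seed = spec$rng_seed + 1L)
}

#' Generate a pair of fixtures sharing part of their module structure
#'
#' Both bundles share the TF/gene universes, gene annotation and window
#' geometry; a fraction of the co-regulatory modules keep identical target
#' sets across the pair while the rest are redrawn, creating
#' context-specific edges for differential analysis.
#'
#' @param spec a [fixtureSpec()].
#' @param shared_module_frac fraction of modules with identical targets in
#'   both fixtures.
#' @return list with elements `A` and `B`, each a `FixtureBundle`.
#' @export
generatePairedFixtures <- function(spec = fixtureSpec(),
                                   shared_module_frac = 0.5) {
  stopifnot(shared_module_frac >= 0, shared_module_frac <= 1)
  targetsA <- .drawModuleTargets(spec)
  n_shared <- round(shared_module_frac * spec$n_modules)
  specB <- spec
  specB$rng_seed <- spec$rng_seed + 1000L
  targetsB <- .drawModuleTargets(specB)
  if (n_shared > 0) targetsB[seq_len(n_shared)] <- targetsA[seq_len(n_shared)]
  list(A = .generateFromModules(spec, targetsA, spec$rng_seed + 1L),
       B = .generateFromModules(spec, targetsB, spec$rng_seed + 2L))
}

#' Write a fixture bundle to disk as plain-text inputs
#'
#' Emits one motif BED6 per TF (`motifs/<TF>.bed`), one ChIP BED per TF
#' (`chip/<TF>.bed`), the open-chromatin BED, the gene annotation TSV, the
#' truth network edge list and a JSON manifest of the generating spec.
#'
#' @param bundle a `FixtureBundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  dir.create(file.path(dir, "motifs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "chip"), showWarnings = FALSE)
  for (tf in names(bundle$motif_sets)) {
    writeBed(bundle$motif_sets[[tf]],
             file.path(dir, "motifs", paste0(tf, ".bed")))
  }
  for (tf in names(bundle$chip_sets)) {
    writeBed(bundle$chip_sets[[tf]],
             file.path(dir, "chip", paste0(tf, ".bed")))
  }
  writeBed(bundle$open_chromatin, file.path(dir, "open_chromatin.bed"))
  utils::write.table(as.data.frame(unclass(bundle$genes)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeEdgeList(bundle$truth, file.path(dir, "truth_network.tsv"))
  spec <- bundle$spec
  spec$window <- unclass(spec$window)
  jsonlite::write_json(unclass(spec), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Run the four-network benchmark on a fixture
#'
#' Builds the naive seed (motifs x windows), the epigenetically informed
#' seed (motifs x open chromatin x windows), and their message-passing
#' refinements, then scores all four against the ChIP-derived gold
#' standard, and measures hidden-edge recovery: the median refined weight
#' of planted hidden edges (true edges whose motif was dropped) versus the
#' median refined weight of absent non-edges.
#'
#' @param bundle a `FixtureBundle`.
#' @param config a [messagePassingConfig()].
#' @param jitter_sigma Gaussian jitter for AUPR of the binary seeds.
#' @return list with `summary` (data.frame of network, auc, aupr),
#'   `networks` (the four networks plus gold), `per_tf` (per-TF results on
#'   the refined epigenetic network) and `hidden` (recovery metrics).
#' @export
fixtureBenchmark <- function(bundle, config = messagePassingConfig(),
                             jitter_sigma = 0.05) {
  genes <- geneNames(bundle$truth)
  tfs <- tfNames(bundle$truth)
  nsn <- buildSeedNetwork(bundle$motif_sets, bundle$windows,
                          open_chromatin = NULL, tf_universe = tfs,
                          gene_universe = genes)
  ssn <- buildSeedNetwork(bundle$motif_sets, bundle$windows,
                          open_chromatin = bundle$open_chromatin,
                          tf_universe = tfs, gene_universe = genes)
  nrn <- runSpider(degreeNormalize(nsn), config)
  srn <- runSpider(degreeNormalize(ssn), config)
  gold <- buildGoldStandard(bundle$chip_sets, bundle$windows,
                            gene_universe = genes)
  nets <- list(NSN = nsn, SSN = ssn, NRN = nrn, SRN = srn)
  evals <- lapply(nets, function(n)
    evaluateNetwork(n, gold,
                    jitter_sigma = if (isBinary(n)) jitter_sigma else 0,
                    seed = bundle$spec$rng_seed))
  summary <- data.frame(network = names(nets),
                        auc = vapply(evals, `[[`, 0, "auc"),
                        aupr = vapply(evals, `[[`, 0, "aupr"),
                        row.names = NULL)

  w <- weightMatrix(srn); tr <- weightMatrix(bundle$truth)
  sd_seed <- weightMatrix(ssn)
  hid_idx <- cbind(match(bundle$hidden_truth_edges$tf, tfs),
                   match(bundle$hidden_truth_edges$gene, genes))
  absent_nonedge <- sd_seed == 0 & tr == 0
  hidden <- list(
    n_hidden = nrow(bundle$hidden_truth_edges),
    median_weight_hidden = if (nrow(hid_idx)) stats::median(w[hid_idx])
                           else NA_real_,
    median_weight_absent_nonedge = stats::median(w[absent_nonedge])
  )
  if (nrow(hid_idx)) {
    lab <- integer(0)
    sc <- c(w[hid_idx], w[absent_nonedge])
    lab <- c(rep(1, nrow(hid_idx)), rep(0, sum(absent_nonedge)))
    hidden$auc_hidden_vs_nonedge <- aucROC(sc, lab)
  }
  list(summary = summary, networks = c(nets, list(gold = gold)),
       evaluations = evals,
       per_tf = perTFEvaluation(srn, gold),
       hidden = hidden)
}
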
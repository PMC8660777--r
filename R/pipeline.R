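# End-to-end orchestration: read inputs, build and refine networks,
# evaluate, and report hidden edges, with a reproducible manifest.

#' Build a run configuration
#'
#' @param motif_dir directory with one motif BED per TF; the TF name is the
#'   file name stem (override with a two-column `name_map` data.frame of
#'   file, tf).
#' @param gene_annotation path to the gene annotation file.
#' @param annotation_format `"tsv"` or `"bed"` (see [readGeneAnnotation()]).
#' @param open_chromatin optional open-chromatin BED; `NULL` switches the
#'   run to naive mode.
#' @param chip_dir optional directory of per-TF ChIP peak BEDs; `NULL`
#'   disables the evaluation stages.
#' @param window a [regulatoryRegionSpec()].
#' @param mp a [messagePassingConfig()].
#' @param jitter_sigma AUPR jitter for binary seed evaluation.
#' @param fdr hidden-edge FDR threshold.
#' @param seed integer seed for all stochastic steps (AUPR jitter).
#' @param out_dir output directory.
#' @param name_map optional data.frame (`file`, `tf`) overriding TF names.
#' @return list of class `RunConfig`.
#' @export
spiderConfig <- function(motif_dir, gene_annotation,
                         annotation_format = "tsv",
                         open_chromatin = NULL, chip_dir = NULL,
                         window = regulatoryRegionSpec(),
                         mp = messagePassingConfig(),
                         jitter_sigma = 0.05, fdr = 0.05, seed = 1L,
                         out_dir = tempfile("spider_run_"),
                         name_map = NULL) {
  structure(list(motif_dir = motif_dir, gene_annotation = gene_annotation,
                 annotation_format = annotation_format,
                 open_chromatin = open_chromatin, chip_dir = chip_dir,
                 window = window, mp = mp, jitter_sigma = jitter_sigma,
                 fdr = fdr, seed = as.integer(seed), out_dir = out_dir,
                 name_map = name_map),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [spiderConfig()]; `window` and
#' `message_passing` are nested maps of the respective constructor
#' arguments.
#'
#' @param path YAML file.
#' @return list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  window <- do.call(regulatoryRegionSpec, as.list(y$window))
  mp <- do.call(messagePassingConfig, as.list(y$message_passing))
  spiderConfig(motif_dir = y$motif_dir,
               gene_annotation = y$gene_annotation,
               annotation_format = if (is.null(y$annotation_format)) "tsv"
                                   else y$annotation_format,
               open_chromatin = y$open_chromatin,
               chip_dir = y$chip_dir,
               window = window, mp = mp,
               jitter_sigma = if (is.null(y$jitter_sigma)) 0.05
                              else y$jitter_sigma,
               fdr = if (is.null(y$fdr)) 0.05 else y$fdr,
               seed = if (is.null(y$seed)) 1L else y$seed,
               out_dir = if (is.null(y$out_dir)) tempfile("spider_run_")
                         else y$out_dir)
}

.readBedDir <- function(dir, name_map = NULL) {
  files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (!length(files)) stop("no BED files in ", dir, call. = FALSE)
  tf <- sub("\\.bed$", "", basename(files))
  if (!is.null(name_map)) {
    m <- match(basename(files), name_map$file)
    tf[!is.na(m)] <- name_map$tf[m[!is.na(m)]]
  }
  stats::setNames(lapply(files, readBed), tf)
}

.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                              auto_unbox = TRUE, force = TRUE, null = "null"),
             tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Stages, in order: read motif BEDs; read gene annotation and build
#' regulatory windows; read open chromatin (if configured); build the seed
#' network; degree-normalize; message-pass; if ChIP data is configured,
#' build the gold standard and write global and per-TF evaluations; write
#' the hidden-edge report. Each stage writes its artifact under
#' `config$out_dir`; the returned manifest records per-stage counts, the
#' seeds used and a hash of the configuration, so identical config and
#' seed give identical outputs.
#'
#' @param config a [spiderConfig()] or [readRunConfig()] result.
#' @return list with `manifest` (written to `manifest.json` too) and
#'   `networks` (seed, seed_normalized, spider, gold or NULL).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  msg <- function(...) message(sprintf("[spidernet] %s", sprintf(...)))

  motif_sets <- .readBedDir(config$motif_dir, config$name_map)
  stages$motifs <- list(n_tfs = length(motif_sets),
                        n_intervals = sum(lengths(motif_sets)))
  msg("read %d motif BEDs (%d intervals)", length(motif_sets),
      sum(lengths(motif_sets)))

  genes <- readGeneAnnotation(config$gene_annotation,
                              config$annotation_format)
  windows <- buildRegulatoryRegions(genes, config$window)
  stages$windows <- list(n_genes = length(unique(genes$gene_id)),
                         n_windows = length(windows))
  msg("built %d regulatory windows for %d genes", length(windows),
      length(unique(genes$gene_id)))

  chromatin <- NULL
  if (!is.null(config$open_chromatin)) {
    chromatin <- readBed(config$open_chromatin)
    checkChromosomeCompatibility(motifs = motif_sets[[1]],
                                 open_chromatin = chromatin,
                                 windows = windows)
    stages$open_chromatin <- list(n_peaks = length(chromatin))
    msg("read %d open-chromatin peaks", length(chromatin))
  } else {
    msg("no open chromatin configured: building the naive seed")
  }

  gene_universe <- sort(unique(genes$gene_id))
  seed <- buildSeedNetwork(motif_sets, windows, chromatin,
                           tf_universe = names(motif_sets),
                           gene_universe = gene_universe)
  writeEdgeList(seed, file.path(config$out_dir, "seed_network.tsv"))
  stages$seed <- list(n_edges = sum(weightMatrix(seed) != 0))
  msg("seed network: %d edges", stages$seed$n_edges)

  seed_norm <- degreeNormalize(seed)
  writeEdgeList(seed_norm,
                file.path(config$out_dir, "seed_network_normalized.tsv"))

  sp <- runSpider(seed_norm, config$mp, details = TRUE)
  spider <- sp$network
  writeEdgeList(spider, file.path(config$out_dir, "spider_network.tsv"))
  stages$message_passing <- list(iterations = sp$iterations,
                                 converged = sp$converged)
  msg("message passing: %d iterations (%s)", sp$iterations,
      if (sp$converged) "converged" else "cap reached")

  gold <- NULL
  if (!is.null(config$chip_dir)) {
    chip_sets <- .readBedDir(config$chip_dir, config$name_map)
    gold <- buildGoldStandard(chip_sets, windows, gene_universe)
    ev <- evaluateNetwork(spider, gold, jitter_sigma = 0)
    ev_seed <- evaluateNetwork(seed, gold,
                               jitter_sigma = config$jitter_sigma,
                               seed = config$seed)
    metrics <- data.frame(
      network = c("seed", "spider"),
      auc = c(ev_seed$auc, ev$auc),
      aupr = c(ev_seed$aupr, ev$aupr),
      n_edges_evaluated = c(ev_seed$n_edges_evaluated,
                            ev$n_edges_evaluated),
      positive_fraction = c(ev_seed$positive_fraction,
                            ev$positive_fraction))
    utils::write.table(metrics,
                       file.path(config$out_dir, "evaluation_global.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(perTFEvaluation(spider, gold),
                       file.path(config$out_dir, "evaluation_per_tf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages$evaluation <- list(n_chip_tfs = length(chip_sets),
                              auc_spider = ev$auc, auc_seed = ev_seed$auc)
    msg("evaluation: spider AUC %.3f, seed AUC %.3f", ev$auc, ev_seed$auc)
  } else {
    stages$evaluation <- list(skipped = TRUE)
    msg("no ChIP directory configured: evaluation stages skipped")
  }

  hidden <- selectHiddenEdges(spider, seed, fdr = config$fdr)
  writeHiddenEdgeReport(hidden,
                        file.path(config$out_dir, "hidden_edges.tsv"),
                        file.path(config$out_dir, "hidden_gene_tally.tsv"))
  stages$hidden <- list(n_candidates = hidden$n_candidates,
                        n_selected = nrow(hidden$edges),
                        weight_cutoff = hidden$weight_cutoff_attained)
  msg("hidden edges: %d selected of %d candidates at FDR %.2f",
      nrow(hidden$edges), hidden$n_candidates, config$fdr)

  manifest <- list(package_version = as.character(
                     utils::packageVersion("spidernet")),
                   config_hash = .configHash(config),
                   seed = config$seed, stages = stages)
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  list(manifest = manifest,
       networks = list(seed = seed, seed_normalized = seed_norm,
                       spider = spider, gold = gold))
}

#' Differential analysis between two pipeline runs
#'
#' Runs (or reuses) two pipelines sharing TF/gene universes, builds the
#' seed, refined and gold differential networks (A - B), and evaluates the
#' seed and refined differentials against the ChIP differential, restricted
#' to factors assayed in both contexts. Antisymmetric by construction:
#' swapping A and B flips all signs and leaves the AUCs unchanged.
#'
#' @param runA,runB either `RunConfig` objects (pipelines are executed) or
#'   results of [runPipeline()]; both must include gold standards.
#' @param out optional path for a TSV report.
#' @return list with `auc_seed`, `auc_spider`, the three differential
#'   networks and the two `EvaluationResult`s.
#' @export
runDifferential <- function(runA, runB, out = NULL) {
  if (inherits(runA, "RunConfig")) runA <- runPipeline(runA)
  if (inherits(runB, "RunConfig")) runB <- runPipeline(runB)
  a <- runA$networks; b <- runB$networks
  if (is.null(a$gold) || is.null(b$gold)) {
    stop("both runs need ChIP data for differential evaluation",
         call. = FALSE)
  }
  common <- intersect(tfNames(a$gold), tfNames(b$gold))
  if (!length(common)) stop("no TFs assayed in both contexts",
                            call. = FALSE)
  sub <- function(net) BipartiteNetwork(
    weightMatrix(net)[common, , drop = FALSE],
    binary = isBinary(net))
  gold_diff <- differentialNetwork(sub(a$gold), sub(b$gold))
  seed_diff <- differentialNetwork(sub(a$seed), sub(b$seed))
  spider_diff <- differentialNetwork(sub(a$spider), sub(b$spider))
  ev_seed <- evaluateDifferential(seed_diff, gold_diff)
  ev_spider <- evaluateDifferential(spider_diff, gold_diff)
  if (!is.null(out)) {
    utils::write.table(data.frame(network = c("seed", "spider"),
                                  auc = c(ev_seed$auc, ev_spider$auc),
                                  n_edges = c(ev_seed$n_edges_evaluated,
                                              ev_spider$n_edges_evaluated)),
                       out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(auc_seed = ev_seed$auc, auc_spider = ev_spider$auc,
       seed_diff = seed_diff, spider_diff = spider_diff,
       gold_diff = gold_diff,
       eval_seed = ev_seed, eval_spider = ev_spider)
}
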
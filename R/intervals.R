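# Interval algebra on GRanges interval sets. All operations ignore strand
# and use >= 1 shared-base overlap under the BED half-open convention.

#' Sort an interval set deterministically
#'
#' Orders by (chromosome name, start, end, label) with chromosome names
#' compared lexicographically, so output order is reproducible regardless
#' of seqlevel ordering.
#'
#' @param x `GRanges` interval set.
#' @return sorted `GRanges`.
#' @export
sortIntervals <- function(x) {
  name <- S4Vectors::mcols(x)$name
  if (is.null(name)) name <- rep("", length(x))
  o <- order(as.character(GenomicRanges::seqnames(x)),
             GenomicRanges::start(x), GenomicRanges::end(x), name)
  x[o]
}

#' Keep intervals of `a` that overlap `b`
#'
#' Returns exactly those intervals of `a` (unchanged, labels and scores
#' retained, duplicates preserved) that share at least one base with some
#' interval of `b` on the same chromosome; strand is ignored. This is the
#' `bedtools intersect -u`-style filter used to prune motif locations to
#' open chromatin.
#'
#' @param a,b `GRanges` interval sets (either may be empty).
#' @return subset of `a`, deterministically sorted.
#' @export
intersectKeepA <- function(a, b) {
  if (!length(a) || !length(b)) return(sortIntervals(a[integer(0)]))
  # disjoint seqlevel sets are a legitimate (empty) query here; the
  # chromosome-dialect check is a separate, explicit validation pass
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE,
                                minoverlap = 1L))
  sortIntervals(a[sort(unique(S4Vectors::queryHits(hits)))])
}

#' Merge overlapping and abutting intervals
#'
#' Returns the minimal set of non-overlapping intervals covering the union
#' of `x`, per chromosome, ignoring strand. Intervals that touch
#' (BED `end == start`) are unified, matching the conventional behavior of
#' `bedtools merge` used to build composite ChIP-seq peak files. Labels and
#' scores are dropped (label set to `label`, score to 1).
#'
#' @param x `GRanges` interval set.
#' @param label label assigned to merged intervals.
#' @return merged, sorted `GRanges`.
#' @export
mergeOverlapping <- function(x, label = "") {
  r <- GenomicRanges::reduce(x, ignore.strand = TRUE, min.gapwidth = 1L)
  S4Vectors::mcols(r)$name <- rep(label, length(r))
  S4Vectors::mcols(r)$score <- rep(1, length(r))
  GenomicRanges::strand(r) <- "*"
  sortIntervals(r)
}

#' Specify gene regulatory windows
#'
#' Proximal mode places one window of total width `2 * proximal_halfwidth`
#' centered on each TSS (default 2 kb total). Distal mode places a pair of
#' windows of width `distal_width` each, starting `distal_inner` bp up- and
#' downstream of the TSS (e.g. inner 20000, width 5000 gives the
#' +/-20-25 kb windows). Placement is symmetric in genomic coordinates;
#' strand never changes it.
#'
#' @param mode `"proximal"` or `"distal"`.
#' @param proximal_halfwidth half-width in bp of the proximal window.
#' @param distal_inner offset in bp of the inner edge of each distal window
#'   from the TSS.
#' @param distal_width width in bp of each distal window.
#' @return list of class `RegulatoryRegionSpec`.
#' @export
regulatoryRegionSpec <- function(mode = c("proximal", "distal"),
                                 proximal_halfwidth = 1000,
                                 distal_inner = 20000,
                                 distal_width = 5000) {
  mode <- match.arg(mode)
  stopifnot(proximal_halfwidth > 0, distal_inner > 0, distal_width > 0)
  structure(list(mode = mode,
                 proximal_halfwidth = as.numeric(proximal_halfwidth),
                 distal_inner = as.numeric(distal_inner),
                 distal_width = as.numeric(distal_width)),
            class = "RegulatoryRegionSpec")
}

#' Build gene regulatory windows around TSSs
#'
#' Proximal: one interval per (gene, TSS) pair,
#' `[tss - halfwidth, tss + halfwidth)`, labeled with the gene id. Distal:
#' two intervals per pair, `[tss - inner - width, tss - inner)` and
#' `[tss + inner, tss + inner + width)`. Windows extending past the
#' chromosome start are clipped at 0 with a warning. Genes with multiple
#' annotated TSSs contribute one window per TSS; identical duplicate
#' windows are removed, so a gene's regulatory region is the union of its
#' windows.
#'
#' @param genes a `GeneAnnotation` (see [geneAnnotation()]).
#' @param spec a [regulatoryRegionSpec()].
#' @return sorted `GRanges` of windows labeled by gene id.
#' @export
buildRegulatoryRegions <- function(genes, spec = regulatoryRegionSpec()) {
  stopifnot(inherits(spec, "RegulatoryRegionSpec"))
  if (!nrow(genes)) stop("empty gene annotation", call. = FALSE)
  if (spec$mode == "proximal") {
    s <- genes$tss - spec$proximal_halfwidth
    e <- genes$tss + spec$proximal_halfwidth
    chrom <- genes$chrom; id <- genes$gene_id
  } else {
    s <- c(genes$tss - spec$distal_inner - spec$distal_width,
           genes$tss + spec$distal_inner)
    e <- c(genes$tss - spec$distal_inner,
           genes$tss + spec$distal_inner + spec$distal_width)
    chrom <- rep(genes$chrom, 2); id <- rep(genes$gene_id, 2)
  }
  if (any(s < 0)) {
    warning(sprintf("%d window(s) clipped at chromosome start",
                    sum(s < 0)), call. = FALSE)
    e <- pmax(e, 0); s <- pmax(s, 0)
  }
  keep <- e > s
  s <- s[keep]; e <- e[keep]; chrom <- chrom[keep]; id <- id[keep]
  key <- paste(chrom, s, e, id, sep = "\r")
  dup <- duplicated(key)
  windows <- intervalSet(chrom[!dup], s[!dup], e[!dup], name = id[!dup])
  sortIntervals(windows)
}
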
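#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

# Interval sets are GRanges with metadata columns `name` (label, character)
# and `score` (numeric). BED coordinates (0-based, half-open) are converted
# to the 1-based closed convention of IRanges on read and back on write, so
# all overlap semantics (>= 1 shared base) carry over unchanged.

.bedStrandIn <- function(s) {
  s[!s %in% c("+", "-")] <- "*"
  s
}

.bedStrandOut <- function(s) {
  s <- as.character(s)
  s[s == "*"] <- "."
  s
}

#' Build an interval set (GRanges) from BED-style vectors
#'
#' Coordinates follow BED conventions: 0-based starts, exclusive ends.
#'
#' @param chrom character chromosome names.
#' @param start,end integer BED coordinates (`start >= 0`, `end > start`).
#' @param name labels (TF name, gene id, ...); recycled.
#' @param score non-negative numeric scores; recycled.
#' @param strand one of `"+"`, `"-"`, `"."`; recycled.
#' @return A `GRanges` with `name` and `score` metadata columns.
#' @export
intervalSet <- function(chrom, start, end, name = "", score = 1,
                        strand = ".") {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("negative start coordinate", call. = FALSE)
  if (any(end <= start)) stop("empty or inverted interval (end <= start)",
                              call. = FALSE)
  if (any(score < 0)) stop("negative score", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = .bedStrandIn(rep_len(as.character(strand), n))
  )
  S4Vectors::mcols(gr)$name <- rep_len(as.character(name), n)
  S4Vectors::mcols(gr)$score <- rep_len(as.numeric(score), n)
  gr
}

#' Read a BED / narrowPeak file into an interval set
#'
#' Accepts BED3 to BED6; columns beyond the sixth (e.g. the narrowPeak
#' signal/summit columns) are ignored. Missing columns 4/5/6 default to
#' `default_label`, score 1 and strand ".". Malformed lines (fewer than 3
#' fields, non-integer coordinates, `end <= start`) raise an error naming
#' the offending line number.
#'
#' @param path path to a tab-separated BED file.
#' @param default_label label assigned when column 4 is absent.
#' @return A `GRanges` interval set (see [intervalSet()]).
#' @export
readBed <- function(path, default_label = "") {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(intervalSet(character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("BED parse error at line %d of %s: fewer than 3 columns",
                 which(nf < 3)[1], path), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d of %s: non-integer coordinates",
                 bad[1], path), call. = FALSE)
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf(
      "BED parse error at line %d of %s: empty interval (end <= start)",
      bad[1], path), call. = FALSE)
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))],
                                 ""), default_label)
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  1)
  score[is.na(score)] <- 1
  strand <- ifelse(nf >= 6, vapply(fields, function(f)
    f[min(6L, length(f))], ""), ".")
  intervalSet(chrom, start, end, name = name, score = score, strand = strand)
}

#' Write an interval set as 6-column BED
#'
#' Writes BED6 (chrom, start, end, name, score, strand) with 0-based
#' half-open coordinates; round-trips byte-identically with [readBed()] for
#' canonical BED6 input (integer-formatted scores preserved as integers).
#'
#' @param x `GRanges` interval set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
  score <- S4Vectors::mcols(x)$score
  if (is.null(score)) score <- rep(1, length(x))
  name <- S4Vectors::mcols(x)$name
  if (is.null(name)) name <- rep("", length(x))
  sc <- vapply(score, function(s) format(s, scientific = FALSE,
                                         trim = TRUE), "")
  lines <- paste(as.character(GenomicRanges::seqnames(x)),
                 format(GenomicRanges::start(x) - 1, scientific = FALSE,
                        trim = TRUE),
                 format(GenomicRanges::end(x), scientific = FALSE,
                        trim = TRUE),
                 name, sc, .bedStrandOut(GenomicRanges::strand(x)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation (gene id, chromosome, TSS, strand)
#'
#' Two formats are supported. `"tsv"`: four tab-separated columns
#' `gene_id, chrom, tss, strand` (no header), with `tss` a 0-based
#' coordinate. `"bed"`: BED6 where the TSS is taken as the interval start
#' for `+` strand genes and the interval end for `-` strand genes (the
#' 5' end of the feature).
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
readGeneAnnotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("gene_id", "chrom", "tss",
                                          "strand"))
  } else {
    gr <- readBed(path)
    minus <- as.character(GenomicRanges::strand(gr)) == "-"
    tss <- ifelse(minus, GenomicRanges::end(gr),
                  GenomicRanges::start(gr) - 1)
    df <- data.frame(gene_id = S4Vectors::mcols(gr)$name,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     tss = tss,
                     strand = ifelse(minus, "-", "+"),
                     stringsAsFactors = FALSE)
  }
  geneAnnotation(df$gene_id, df$chrom, df$tss, df$strand)
}

#' Construct a gene annotation table
#'
#' @param gene_id character gene identifiers. Duplicates are allowed
#'   (multiple isoform TSSs per gene); window construction emits one window
#'   per (gene, TSS) pair and de-duplicates identical windows.
#' @param chrom chromosome names.
#' @param tss 0-based transcriptional start site coordinates.
#' @param strand `"+"` or `"-"` (recycled; informational only — window
#'   placement is symmetric about the TSS).
#' @return data.frame of class `GeneAnnotation`.
#' @export
geneAnnotation <- function(gene_id, chrom, tss, strand = "+") {
  tss <- as.numeric(tss)
  if (any(tss < 0)) stop("negative TSS coordinate", call. = FALSE)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   tss = tss,
                   strand = rep_len(as.character(strand), length(gene_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Report chromosome-name compatibility across interval inputs
#'
#' Chromosome naming dialects ("chr1" vs "1") are never silently
#' normalized; this validation pass warns when two inputs share no
#' chromosome names at all (a near-certain dialect mismatch).
#'
#' @param ... named `GRanges` interval sets.
#' @return invisibly, a list of the chromosome-name sets.
#' @export
checkChromosomeCompatibility <- function(...) {
  sets <- list(...)
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("input", seq_along(sets))
  chr <- lapply(sets, function(g)
    unique(as.character(GenomicRanges::seqnames(g))))
  if (length(chr) > 1) {
    for (i in seq_len(length(chr) - 1)) {
      for (j in (i + 1):length(chr)) {
        if (length(chr[[i]]) && length(chr[[j]]) &&
            !length(intersect(chr[[i]], chr[[j]]))) {
          warning(sprintf(
            "chromosome names of '%s' and '%s' do not intersect (dialect mismatch?)",
            nm[i], nm[j]), call. = FALSE)
        }
      }
    }
  }
  invisible(stats::setNames(chr, nm))
}
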
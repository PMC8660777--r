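# TSV import/export for bipartite networks: long edge-list form
# (tf, gene, weight) and dense matrix form with header row/column. Both
# round-trip exactly (weights written with full double precision).

#' Write a network as a TSV edge list
#'
#' Three columns `tf`, `gene`, `weight` with a header line; every cell of
#' the dense matrix is written (including zeros) so the axes round-trip.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  w <- weightMatrix(net)
  df <- data.frame(tf = rep(rownames(w), times = ncol(w)),
                   gene = rep(colnames(w), each = nrow(w)),
                   weight = format(as.vector(w), digits = 17, trim = TRUE,
                                   scientific = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list into a network
#'
#' @param path file written by [writeEdgeList()] (or any headered
#'   tf/gene/weight TSV covering a full grid).
#' @return a [BipartiteNetwork-class].
#' @export
readEdgeList <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric"))
  tfs <- unique(df$tf); genes <- unique(df$gene)
  w <- matrix(0, length(tfs), length(genes),
              dimnames = list(tfs, genes))
  w[cbind(match(df$tf, tfs), match(df$gene, genes))] <- df$weight
  BipartiteNetwork(w, binary = all(w %in% c(0, 1)))
}

#' Write a network as a dense TSV matrix
#'
#' First row holds gene names, first column TF names.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDenseNetwork <- function(net, path) {
  w <- weightMatrix(net)
  m <- matrix(format(w, digits = 17, trim = TRUE, scientific = FALSE),
              nrow(w), dimnames = dimnames(w))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a dense TSV matrix into a network
#'
#' @param path file written by [writeDenseNetwork()].
#' @return a [BipartiteNetwork-class].
#' @export
readDenseNetwork <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  BipartiteNetwork(m, binary = all(m %in% c(0, 1)))
}
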
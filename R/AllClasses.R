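#' @import methods
#' @importFrom stats pnorm p.adjust rnorm runif setNames
#' @importFrom utils read.table write.table head
#' @importFrom jsonlite write_json toJSON
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
NULL

#' BipartiteNetwork: a weighted TF-by-gene regulatory network
#'
#' The central container of the package: a dense \code{N_TF x N_G} weight
#' matrix with ordered, unique transcription factor (row) and gene (column)
#' name axes. The same class carries motif-derived seed networks (binary),
#' degree-normalized seeds, message-passing output networks (weights on a
#' Z-score-like scale), ChIP-derived gold standards, and differential
#' networks.
#'
#' @slot weights numeric matrix, rows = transcription factors, columns =
#'   genes; \code{dimnames} hold the two name axes.
#' @slot binary logical; \code{TRUE} asserts all weights are exactly 0 or 1.
#' @slot metadata character; free-text provenance.
#'
#' @seealso [BipartiteNetwork()], [tfNames()], [geneNames()], [weightMatrix()]
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
  representation(
    weights = "matrix",
    binary = "logical",
    metadata = "character"
  ),
  prototype(
    weights = matrix(numeric(0), 0, 0),
    binary = FALSE,
    metadata = ""
  )
)

setValidity("BipartiteNetwork", function(object) {
  w <- object@weights
  msgs <- character(0)
  if (!is.numeric(w)) {
    msgs <- c(msgs, "weights must be a numeric matrix")
  }
  dn <- dimnames(w)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]])) {
    msgs <- c(msgs, "weights must carry TF (row) and gene (column) dimnames")
  } else {
    if (anyDuplicated(dn[[1]])) {
      msgs <- c(msgs, "duplicate TF names on the row axis")
    }
    if (anyDuplicated(dn[[2]])) {
      msgs <- c(msgs, "duplicate gene names on the column axis")
    }
  }
  if (length(object@binary) != 1L || is.na(object@binary)) {
    msgs <- c(msgs, "binary must be TRUE or FALSE")
  } else if (isTRUE(object@binary) && length(w) && !all(w %in% c(0, 1))) {
    msgs <- c(msgs, "binary network has weights outside {0, 1}")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BipartiteNetwork
#'
#' @param weights numeric matrix (TFs x genes). If `tfs`/`genes` are given
#'   they are applied as dimnames; otherwise `weights` must already carry
#'   dimnames.
#' @param tfs,genes optional character vectors of row/column names.
#' @param binary logical; declare the network binary (validated).
#' @param metadata free-text provenance string.
#' @return A [BipartiteNetwork-class] object.
#' @examples
#' w <- matrix(c(1, 0, 1, 1), 2, 2)
#' net <- BipartiteNetwork(w, tfs = c("TF1", "TF2"), genes = c("g1", "g2"),
#'                         binary = TRUE)
#' tfNames(net)
#' @export
BipartiteNetwork <- function(weights, tfs = NULL, genes = NULL,
                             binary = FALSE, metadata = "") {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (!is.null(tfs)) rownames(weights) <- as.character(tfs)
  if (!is.null(genes)) colnames(weights) <- as.character(genes)
  new("BipartiteNetwork", weights = weights, binary = binary,
      metadata = metadata)
}

#' @describeIn BipartiteNetwork transcription factor (row) names.
#' @param x,object a `BipartiteNetwork`.
#' @export
tfNames <- function(x) rownames(x@weights)

#' @describeIn BipartiteNetwork gene (column) names.
#' @export
geneNames <- function(x) colnames(x@weights)

#' @describeIn BipartiteNetwork the dense weight matrix.
#' @export
weightMatrix <- function(x) x@weights

#' @describeIn BipartiteNetwork whether the network is declared binary.
#' @export
isBinary <- function(x) x@binary

setMethod("show", "BipartiteNetwork", function(object) {
  w <- object@weights
  cat(sprintf("BipartiteNetwork: %d TFs x %d genes (%s)\n",
              nrow(w), ncol(w),
              if (object@binary) "binary" else "weighted"))
  if (length(w)) {
    cat(sprintf("  nonzero edges: %d / %d\n", sum(w != 0), length(w)))
    cat(sprintf("  weight range: [%.4g, %.4g]\n", min(w), max(w)))
  }
  if (nzchar(object@metadata)) cat("  metadata:", object@metadata, "\n")
  invisible(object)
})

#' @describeIn BipartiteNetwork dimensions `c(N_TF, N_G)`.
#' @export
setMethod("dim", "BipartiteNetwork", function(x) dim(x@weights))

# Internal: check two networks share both axes exactly.
.checkSameAxes <- function(a, b) {
  if (!identical(tfNames(a), tfNames(b)) ||
      !identical(geneNames(a), geneNames(b))) {
    stop("networks do not share identical TF and gene axes", call. = FALSE)
  }
  invisible(TRUE)
}
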
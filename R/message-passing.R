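# PANDA-style message passing on a (W, P, C) network triple, and the
# SPIDER driver that runs it with identity cooperativity/co-regulation
# priors.

#' Configure the message-passing iteration
#'
#' @param alpha update step size in (0, 1]; each iteration moves the
#'   matrices a fraction `alpha` toward their similarity-based estimates
#'   (0 is accepted for testing: the fixed-point case).
#' @param tol convergence threshold on the mean absolute element-wise
#'   change of W between iterations.
#' @param max_iter iteration cap.
#' @param std_mode `"sample"` (n-1 denominator) or `"population"` (n) for
#'   the standard deviations in the Z-score normalization.
#' @param normalize_priors apply the Z-score normalization to P and C as
#'   well as W (the default; identity priors included). `FALSE` leaves P
#'   and C on their input scale.
#' @param update_diagonal stabilize the self-similarity diagonals of P and
#'   C after each update by replacing them with
#'   `n * exp(2 * alpha * step) * sd(off-diagonal column entries)`, the
#'   convention of the reference message-passing implementations. The
#'   growing diagonal progressively dominates the Tanimoto denominators,
#'   damping the updates and forcing convergence; without it the iteration
#'   diverges geometrically (see the methods vignette). `FALSE` applies the
#'   update equations literally.
#' @return list of class `MessagePassingConfig`.
#' @export
messagePassingConfig <- function(alpha = 0.1, tol = 1e-3, max_iter = 100,
                                 std_mode = c("sample", "population"),
                                 normalize_priors = TRUE,
                                 update_diagonal = TRUE) {
  std_mode <- match.arg(std_mode)
  stopifnot(alpha >= 0, alpha <= 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 std_mode = std_mode,
                 normalize_priors = isTRUE(normalize_priors),
                 update_diagonal = isTRUE(update_diagonal)),
            class = "MessagePassingConfig")
}

# Reference-family diagonal stabilization: the diagonal of a square
# similarity matrix is replaced by the per-column standard deviation of
# the off-diagonal entries times n * exp(2 * alpha * step).
.stabilizeDiagonal <- function(mat, alpha, step) {
  n <- nrow(mat)
  d <- mat
  diag(d) <- NA
  pos <- apply(d, 2, stats::sd, na.rm = TRUE)
  pos[is.na(pos)] <- 0
  diag(mat) <- pos * n * exp(2 * alpha * step)
  mat
}

#' Two-way Z-score normalization of a matrix
#'
#' Each entry is replaced by the average of its row-wise and column-wise
#' Z-scores, scaled by 1/sqrt(2):
#' `X0_ij = ((X_ij - mu_i)/sigma_i + (X_ij - mu_j)/sigma_j) / sqrt(2)`.
#' A row or column with zero standard deviation contributes 0 for its term
#' (dense seed networks necessarily contain all-zero rows/columns).
#'
#' @param X finite numeric matrix.
#' @param std_mode `"sample"` or `"population"` standard deviation.
#' @return normalized matrix of the same shape.
#' @export
zscoreNormalize <- function(X, std_mode = c("sample", "population")) {
  std_mode <- match.arg(std_mode)
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  mu_r <- rowMeans(X); mu_c <- colMeans(X)
  if (std_mode == "sample") {
    sd_r <- sqrt(rowSums((X - mu_r)^2) / max(m - 1, 1))
    sd_c <- sqrt(colSums(sweep(X, 2, mu_c)^2) / max(n - 1, 1))
  } else {
    sd_r <- sqrt(rowSums((X - mu_r)^2) / m)
    sd_c <- sqrt(colSums(sweep(X, 2, mu_c)^2) / n)
  }
  zr <- (X - mu_r) / ifelse(sd_r > 0, sd_r, Inf)
  zc <- sweep(sweep(X, 2, mu_c), 2, ifelse(sd_c > 0, sd_c, Inf), `/`)
  (zr + zc) / sqrt(2)
}

#' Continuous Tanimoto similarity between matrix rows and columns
#'
#' `T_ij = (x . y) / sqrt(||x||^2 + ||y||^2 - |x . y|)` where x is row i of
#' X and y is column j of Y. For x = y this reduces to ||x||, so the
#' similarity of a vector with itself is its length. Entries whose
#' denominator is zero (both vectors all-zero) are set to 0.
#'
#' @param X numeric matrix whose rows are the left vectors.
#' @param Y numeric matrix whose columns are the right vectors;
#'   `ncol(X) == nrow(Y)`.
#' @return `nrow(X) x ncol(Y)` similarity matrix.
#' @export
tanimotoSimilarity <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != nrow(Y)) {
    stop("dimension mismatch: ncol(X) != nrow(Y)", call. = FALSE)
  }
  dot <- X %*% Y
  den2 <- outer(rowSums(X^2), colSums(Y^2), `+`) - abs(dot)
  den <- sqrt(pmax(den2, 0))
  out <- dot / den
  out[den == 0] <- 0
  out
}

#' Run message passing on a (W, P, C) triple
#'
#' All three matrices are first Z-score normalized (see
#' [zscoreNormalize()]; P and C only when `normalize_priors`). Each
#' iteration then (1) moves W toward the average of the TF-cooperativity
#' message `T(P, W)` and the gene-co-regulation message `t(T(C, t(W)))`,
#' and (2) re-estimates P and C from the updated W as the Tanimoto
#' similarity of its rows (shared targets) and columns (shared
#' regulators):
#' \deqn{W_t = (1 - a) W_{t-1} + (a/2)(T(P_{t-1}, W_{t-1}) +
#'       T(C_{t-1}, W_{t-1}')')}
#' \deqn{P_t = (1 - a) P_{t-1} + a T(W_t, W_t'),\quad
#'       C_t = (1 - a) C_{t-1} + a T(W_t', W_t)}
#' Iteration stops when the mean absolute change of W drops below `tol`
#' or at `max_iter`.
#'
#' @param W `N_TF x N_G` regulatory matrix (or [BipartiteNetwork-class]).
#' @param P `N_TF x N_TF` TF cooperativity prior.
#' @param C `N_G x N_G` gene co-regulation prior.
#' @param config a [messagePassingConfig()].
#' @return list of class `MessagePassingResult` with elements `W` (final
#'   matrix, dimnames preserved), `iterations`, `trace` (per-iteration mean
#'   absolute change) and `converged`.
#' @export
runMessagePassing <- function(W, P, C, config = messagePassingConfig()) {
  stopifnot(inherits(config, "MessagePassingConfig"))
  if (is(W, "BipartiteNetwork")) W <- weightMatrix(W)
  W <- as.matrix(W); P <- as.matrix(P); C <- as.matrix(C)
  if (nrow(P) != ncol(P) || ncol(C) != nrow(C)) {
    stop("P and C must be square", call. = FALSE)
  }
  if (nrow(P) != nrow(W) || nrow(C) != ncol(W)) {
    stop("P/C dimensions inconsistent with W", call. = FALSE)
  }
  dn <- dimnames(W)
  alpha <- config$alpha
  W <- zscoreNormalize(W, config$std_mode)
  if (config$normalize_priors) {
    P <- zscoreNormalize(P, config$std_mode)
    C <- zscoreNormalize(C, config$std_mode)
  }
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(config$max_iter)) {
    iter <- t
    Wnew <- (1 - alpha) * W +
      (alpha / 2) * (tanimotoSimilarity(P, W) +
                       t(tanimotoSimilarity(C, t(W))))
    if (any(!is.finite(Wnew))) {
      stop("non-finite values in W at iteration ", t, call. = FALSE)
    }
    delta <- mean(abs(Wnew - W))
    trace <- c(trace, delta)
    Pupd <- tanimotoSimilarity(Wnew, t(Wnew))
    Cupd <- tanimotoSimilarity(t(Wnew), Wnew)
    if (config$update_diagonal) {
      Pupd <- .stabilizeDiagonal(Pupd, alpha, t - 1L)
      Cupd <- .stabilizeDiagonal(Cupd, alpha, t - 1L)
    }
    P <- (1 - alpha) * P + alpha * Pupd
    C <- (1 - alpha) * C + alpha * Cupd
    W <- Wnew
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(W) <- dn
  structure(list(W = W, iterations = iter, trace = trace,
                 converged = converged),
            class = "MessagePassingResult")
}

#' Refine a degree-normalized seed network (SPIDER step 4)
#'
#' Runs message passing with the TF cooperativity and gene co-regulation
#' priors both set to the identity matrix and W set to the
#' degree-normalized seed A*. The output is a complete weighted bipartite
#' network whose edge-weight distribution behaves like Z-scores; high
#' weights on edges absent from the seed are candidate hidden
#' interactions.
#'
#' @param seed_normalized the output of [degreeNormalize()].
#' @param config a [messagePassingConfig()].
#' @param details if `TRUE`, return the full `MessagePassingResult` with a
#'   `network` element; otherwise (default) just the refined
#'   [BipartiteNetwork-class].
#' @return a [BipartiteNetwork-class], or a list when `details = TRUE`.
#' @export
runSpider <- function(seed_normalized, config = messagePassingConfig(),
                      details = FALSE) {
  w <- weightMatrix(seed_normalized)
  res <- runMessagePassing(w, diag(nrow(w)), diag(ncol(w)), config)
  net <- BipartiteNetwork(res$W, binary = FALSE,
                          metadata = sprintf(
                            "message-passing network (%d iterations, %s)",
                            res$iterations,
                            if (res$converged) "converged" else
                              "iteration cap reached"))
  if (details) c(list(network = net), unclass(res)) else net
}
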
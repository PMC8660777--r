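# Independent brute-force oracles and small generators used across the
# suite. These deliberately avoid the package's vectorized/GRanges code
# paths: plain loops over plain data.frames.

# Random BED-style intervals as a data.frame (0-based half-open).
randomIntervalDf <- function(n, seed, max_pos = 1e4, max_width = 50,
                             chroms = c("chr1", "chr2", "chr3")) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             name = sprintf("iv%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

dfToIntervals <- function(df) {
  intervalSet(df$chrom, df$start, df$end, name = df$name)
}

intervalsToDf <- function(x) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
             start = GenomicRanges::start(x) - 1L,
             end = GenomicRanges::end(x),
             name = S4Vectors::mcols(x)$name,
             stringsAsFactors = FALSE)
}

# O(|a| * |b|) all-pairs overlap filter (half-open semantics).
bruteIntersectKeepA <- function(a, b) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  a[keep, , drop = FALSE]
}

# Per-base occupancy merge oracle; coordinates must stay small.
bruteMerge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    occ <- logical(max(sub$end))
    for (i in seq_len(nrow(sub))) {
      occ[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    r <- rle(occ)
    pos <- cumsum(c(0, r$lengths))
    runs <- which(r$values)
    for (k in runs) {
      out[[length(out) + 1]] <- data.frame(chrom = ch,
                                           start = pos[k], end = pos[k + 1],
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Triple-loop seed-network oracle over (motif, peak, window) tuples.
bruteSeed <- function(motif_dfs, windows_df, chromatin_df, tfs, genes) {
  w <- matrix(0, length(tfs), length(genes),
              dimnames = list(tfs, genes))
  overlaps <- function(c1, s1, e1, c2, s2, e2) {
    c1 == c2 && s1 < e2 && e1 > s2
  }
  for (tf in names(motif_dfs)) {
    m <- motif_dfs[[tf]]
    for (i in seq_len(nrow(m))) {
      in_chromatin <- is.null(chromatin_df)
      if (!in_chromatin) {
        for (k in seq_len(nrow(chromatin_df))) {
          if (overlaps(m$chrom[i], m$start[i], m$end[i],
                       chromatin_df$chrom[k], chromatin_df$start[k],
                       chromatin_df$end[k])) {
            in_chromatin <- TRUE
            break
          }
        }
      }
      if (!in_chromatin) next
      for (j in seq_len(nrow(windows_df))) {
        if (overlaps(m$chrom[i], m$start[i], m$end[i],
                     windows_df$chrom[j], windows_df$start[j],
                     windows_df$end[j])) {
          w[tf, windows_df$name[j]] <- 1
        }
      }
    }
  }
  w
}

# Pairwise-enumeration AUC oracle.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Definition-level O(m^2) Benjamini-Hochberg oracle.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(k) m * p[o[k]] / k, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# Loop-free is the package; this oracle is the opposite: explicit scalar
# loops transcribing the z-score, similarity and first W update formulas.
oracleZscore <- function(X, sample_sd = TRUE) {
  n <- nrow(X); m <- ncol(X)
  out <- matrix(0, n, m)
  denom_r <- if (sample_sd) m - 1 else m
  denom_c <- if (sample_sd) n - 1 else n
  for (i in seq_len(n)) for (j in seq_len(m)) {
    mu_i <- mean(X[i, ]); si <- sqrt(sum((X[i, ] - mu_i)^2) / denom_r)
    mu_j <- mean(X[, j]); sj <- sqrt(sum((X[, j] - mu_j)^2) / denom_c)
    ti <- if (si > 0) (X[i, j] - mu_i) / si else 0
    tj <- if (sj > 0) (X[i, j] - mu_j) / sj else 0
    out[i, j] <- (ti + tj) / sqrt(2)
  }
  out
}

oracleTanimoto <- function(X, Y) {
  out <- matrix(0, nrow(X), ncol(Y))
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(Y))) {
    x <- X[i, ]; y <- Y[, j]
    d <- sum(x * y)
    den <- sqrt(sum(x^2) + sum(y^2) - abs(d))
    out[i, j] <- if (den > 0) d / den else 0
  }
  out
}

oracleOneStep <- function(W, P, C, alpha, sample_sd = TRUE) {
  W0 <- oracleZscore(W, sample_sd)
  P0 <- oracleZscore(P, sample_sd)
  C0 <- oracleZscore(C, sample_sd)
  (1 - alpha) * W0 +
    (alpha / 2) * (oracleTanimoto(P0, W0) + t(oracleTanimoto(C0, t(W0))))
}

# Small ready-made bipartite networks for evaluation tests.
makeNet <- function(w, binary = FALSE) {
  BipartiteNetwork(w,
                   tfs = sprintf("TF%02d", seq_len(nrow(w))),
                   genes = sprintf("g%03d", seq_len(ncol(w))),
                   binary = binary)
}
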
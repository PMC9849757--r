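# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Step-up BH by direct enumeration: q_(i) = min_{j >= i} m * p_(j) / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(m * ps[i:m] / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Natural connectivity via the matrix exponential trace (Matrix::expm),
# independent of the eigen-decomposition route.
natcon_expm <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  a[a != 0] <- 1
  n <- nrow(a)
  log(sum(diag(as.matrix(Matrix::expm(Matrix::Matrix(a))))) / n)
}

# All-pairs shortest paths by breadth-first search on an adjacency matrix.
bfs_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(a[v, ] > 0)
        new <- nb[d[s, nb] == Inf]
        d[s, new] <- depth
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

efficiency_brute <- function(a) {
  n <- nrow(a)
  d <- bfs_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

vulnerability_brute <- function(a) {
  e0 <- efficiency_brute(a)
  n <- nrow(a)
  drops <- vapply(seq_len(n), function(i) {
    ai <- a
    ai[i, ] <- 0
    ai[, i] <- 0
    (e0 - efficiency_brute(ai)) / e0
  }, numeric(1))
  max(drops)
}

# Spreadsheet-style entropy-weighted multifunctionality: every step written
# out longhand.
entropy_mf_brute <- function(mat) {
  n <- nrow(mat)
  J <- ncol(mat)
  xn <- mat
  for (j in seq_len(J)) {
    lo <- min(mat[, j]); hi <- max(mat[, j])
    xn[, j] <- if (hi > lo) (mat[, j] - lo) / (hi - lo) else 0
  }
  d <- numeric(J)
  for (j in seq_len(J)) {
    s <- sum(xn[, j])
    if (s == 0) { d[j] <- 0; next }
    e <- 0
    for (i in seq_len(n)) {
      pij <- xn[i, j] / s
      if (pij > 0) e <- e - pij * log(pij)
    }
    d[j] <- 1 - e / log(n)
  }
  w <- if (sum(d) > 0) d / sum(d) else rep(1 / J, J)
  mf <- numeric(n)
  for (i in seq_len(n)) mf[i] <- sum(w * xn[i, ])
  list(mf = mf, weights = w)
}

# Textbook Pearson r and two-sided p.
pearson_brute <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

# Partial correlation via the residual route: correlate residuals of x ~ z
# and y ~ z.
partial_resid_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Two-sample KS statistic as the maximal ECDF gap, by enumeration.
ks_stat_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Per-taxon SIMPER contributions by explicit pair-by-pair decomposition.
simper_brute <- function(tab, groups) {
  groups <- as.factor(groups)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  acc <- numeric(nrow(tab)); np <- 0
  for (i in ia) for (j in ib) {
    den <- sum(tab[, i] + tab[, j])
    acc <- acc + abs(tab[, i] - tab[, j]) / den
    np <- np + 1
  }
  contr <- acc / np
  sort(100 * contr / sum(contr), decreasing = TRUE)
}

# Small deterministic graphs used in several files.
toy_path3 <- function() igraph::make_graph(~ a - b, b - c)
toy_path4 <- function() igraph::make_graph(~ a - b, b - c, c - d)
toy_k <- function(n) igraph::make_full_graph(n)
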
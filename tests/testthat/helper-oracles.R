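# Independent brute-force oracles used across the suite. These stay
# deliberately naive: they re-derive the quantities the package computes
# by a different route (normal equations, exhaustive enumeration,
# explicit agglomeration) so that agreement is informative.

# OLS by explicit normal equations, with the beta4 standard error
oracleNormalEquations <- function(g, m, p) {
  keep <- !is.na(m) & !is.na(g)
  g <- g[keep]; m <- m[keep]; p <- p[keep]
  X <- cbind(1, g, p, g * p)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% m)
  res <- m - X %*% beta
  df <- length(m) - 4L
  s2 <- sum(res^2) / df
  se4 <- sqrt(s2 * solve(XtX)[4L, 4L])
  list(beta = as.vector(beta), se4 = se4,
       t4 = beta[4L] / se4,
       p4 = 2 * pt(-abs(beta[4L] / se4), df))
}

# per-group simple-regression slopes; their difference equals beta4
oracleSlopeDiff <- function(g, m, p) {
  keep <- !is.na(m) & !is.na(g)
  g <- g[keep]; m <- m[keep]; p <- p[keep]
  s1 <- coef(lm(m[p == 0] ~ g[p == 0]))[2L]
  s2 <- coef(lm(m[p == 1] ~ g[p == 1]))[2L]
  unname(s2 - s1)
}

# exact hypergeometric upper tail by combinatorial summation
oracleHyperTail <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  ok <- (n - j) <= (N - K)
  sum(choose(K, j[ok]) * choose(N - K, n - j[ok])) / choose(N, n)
}

# naive complete-linkage agglomeration: returns the sequence of merge
# heights and the partition after each merge
oracleCompleteLinkage <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric()
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < best[1L]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1L])
    merged <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters <- c(clusters[-c(best[2L], best[3L])], list(merged))
    partitions[[length(partitions) + 1L]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (list of index sets) for comparison
canonicalPartition <- function(p) {
  s <- lapply(p, sort)
  s[order(vapply(s, `[`, numeric(1L), 1L))]
}

# permutations of 1:8 with known Sum d^2 against the identity, giving
# each rank-correlation magnitude on the n = 8 grid (derived by hand
# from disjoint transpositions/cycles; Sum d^2 shown alongside)
rankGridPermutations <- list(
  list(perm = c(2, 1, 4, 3, 5, 6, 7, 8), sumd2 = 4),    # r = 0.952
  list(perm = c(3, 2, 1, 4, 5, 6, 7, 8), sumd2 = 8),    # r = 0.905
  list(perm = c(3, 2, 1, 5, 4, 7, 6, 8), sumd2 = 12),   # r = 0.857
  list(perm = c(2, 3, 1, 6, 5, 4, 7, 8), sumd2 = 14),   # r = 0.833
  list(perm = c(3, 2, 1, 6, 5, 4, 7, 8), sumd2 = 16),   # r = 0.810
  list(perm = c(4, 2, 3, 1, 6, 5, 7, 8), sumd2 = 20)    # r = 0.762
)

# small complete two-group dataset for integration tests
makePairFixture <- function(seed, n = 8L, beta = c(1, -1, 1, 2),
                            noise = 0.5, missing = 0L) {
  set.seed(seed)
  p <- rep(0:1, each = n)
  g <- rnorm(2 * n, mean = 8)
  m <- beta[1] + beta[2] * g + beta[3] * p + beta[4] * g * p +
    rnorm(2 * n, 0, noise)
  if (missing > 0L) m[sample(2 * n, missing)] <- NA
  list(g = g, m = m, p = p)
}
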
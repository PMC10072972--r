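# Independent oracles, deliberately naive: direct transcriptions of the
# defining formulas, kept free of any package internals.

# two-line PLI: wrap each phase difference into (-pi, pi], signum, mean, abs
refPLI <- function(phase_x, phase_y) {
  s <- numeric(length(phase_x))
  for (n in seq_along(phase_x)) {
    d <- phase_x[n] - phase_y[n]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    s[n] <- if (d > 0) 1 else if (d < 0) -1 else 0
  }
  abs(mean(s))
}

# Floyd-Warshall all-pairs shortest paths on inverse-weight distances
refDistances <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) d[i, j] <- 1 / W[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

refGlobalEfficiency <- function(W) {
  d <- refDistances(W)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

refPathLength <- function(W) {
  d <- refDistances(W)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# leading eigenvector by dense eigendecomposition, non-negative, unit norm
refEigenCentrality <- function(W) {
  e <- eigen(W, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# one-way ANOVA from explicit sums of squares
refAnovaF <- function(values, groups) {
  groups <- factor(groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

randomWeightedGraph <- function(n, density = 0.6) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- sample(ut, ceiling(density * length(ut)))
  W[on] <- runif(length(on), 0.05, 1)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}
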
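# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and explicit formulas, not the code
# paths they verify.

# O(n * w) running-quantile background subtraction.
brute_running_quantile <- function(coord, x, window, q) {
  half <- window / 2
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    inside <- abs(coord - coord[i]) <= half
    out[i] <- max(0, x[i] - quantile(x[inside], q, names = FALSE))
  }
  out
}

# Mann-Whitney U statistic for group a by pairwise win counting.
brute_u_stat <- function(a, b) {
  u <- 0
  for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
  u
}

# Step-up Benjamini-Hochberg by the textbook recipe.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Spearman rho via explicit mean-tied ranks and the Pearson formula.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Clearance-grid scorer: plateau-then-line least squares per gene via
# explicit normal-equation sums, mean R^2 across genes per candidate.
brute_clearance_profile <- function(series, grid) {
  genes <- split(series, series$gene)
  vapply(grid, function(v) {
    scores <- vapply(genes, function(g) {
      keep <- g$abundance > 0
      t <- g$time_s[keep]; y <- log(g$abundance[keep])
      lag <- g$distance[1] / v
      if (sum(t > lag) < 2) return(-Inf)
      x <- pmax(0, t - lag)
      sxx <- sum((x - mean(x))^2)
      syy <- sum((y - mean(y))^2)
      if (syy == 0) return(1)
      if (sxx == 0) return(0)
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      b <- sxy / sxx
      a <- mean(y) - b * mean(x)
      sse <- sum((y - a - b * x)^2)
      1 - sse / syy
    }, numeric(1))
    if (any(!is.finite(scores))) -Inf else mean(scores)
  }, numeric(1))
}

# Zero-intercept least squares by grid refinement of sum((y - s x)^2).
brute_zero_intercept_slope <- function(x, y, lo = -10, hi = 10) {
  for (iter in 1:6) {
    s <- seq(lo, hi, length.out = 401)
    sse <- vapply(s, function(si) sum((y - si * x)^2), numeric(1))
    best <- s[which.min(sse)]
    span <- (hi - lo) / 40
    lo <- best - span; hi <- best + span
  }
  best
}
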
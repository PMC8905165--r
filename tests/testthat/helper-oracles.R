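# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dynamic-programming segmentation, closed-form
# Wilson/Welch formulas, and exhaustive small-n enumeration.

# Exact optimal segmentation by dynamic programming, with the same Schwarz
# criterion and step-counting rule as count_steps() but a globally optimal
# (not greedy) search over change-point placements.
dp_count_steps <- function(y, max_steps = 8L, min_step = NULL) {
  n <- length(y)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    max(cs2[j + 1] - cs2[i] - s^2 / (j - i + 1), 0)
  }
  K <- max_steps + 1L  # segments
  cost <- matrix(Inf, K, n)
  back <- matrix(0L, K, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (K > 1) for (k in 2:K) for (j in k:n) {
    for (t in (k - 1):(j - 1)) {
      c2 <- cost[k - 1, t] + sse(t + 1, j)
      if (c2 < cost[k, j]) { cost[k, j] <- c2; back[k, j] <- t }
    }
  }
  eps <- max(1e-12, 1e-12 * stats::var(y) * n)
  pen <- 2 * log(n)
  crit <- sapply(1:K, function(k) n * log(max(cost[k, n], eps) / n) + (k - 1) * pen)
  k <- which.min(crit)
  bounds <- n
  if (k > 1) { j <- n; for (kk in k:2) { t <- back[kk, j]; bounds <- c(t, bounds); j <- t } }
  bounds <- c(0L, bounds)
  segs <- cbind(bounds[-length(bounds)] + 1L, bounds[-1L])
  levels <- apply(segs, 1L, function(ij) mean(y[ij[1]:ij[2]]))
  drops <- -diff(levels)
  down <- drops[drops > 0]
  ms <- if (!is.null(min_step)) min_step
  else if (length(down)) 0.5 * stats::median(down) else Inf
  sum(drops >= ms & drops > 0)
}

# Wilson score interval, straight from the closed form.
wilson_ci <- function(x, n, z = qnorm(0.975)) {
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(centre - half, centre + half)
}

# Welch's t from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Noiseless bleaching staircase of k unit steps with given segment lengths.
staircase <- function(levels, len = 6L, unit = 200) rep(levels * unit, each = len)

# Standard fixtures
fixture_optics <- function(...) optics_model(...)

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
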
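# Independent oracles used across the suite. Each one is a deliberately
# naive, brute-force or direct-formula implementation kept separate from the
# package's code paths.

# Average ranks by explicit enumeration: for each element, 1 + number of
# smaller elements + half the number of equal others.
bruteforce_ranks <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }, numeric(1))
}

# Spearman rho via explicit rank formula and raw-moment Pearson sums.
bruteforce_spearman <- function(x, y) {
  rx <- bruteforce_ranks(x)
  ry <- bruteforce_ranks(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Direct transcription of the independent-samples Fisher z comparison.
oracle_fisher_z <- function(r1, n1, r2, n2) {
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

# Direct transcription of Steiger's (1980) pooled-rbar statistic for two
# overlapping dependent correlations.
oracle_steiger_z <- function(r_1c, r_2c, r_12, n) {
  rb <- (r_1c + r_2c) / 2
  psi <- r_12 * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r_12^2)
  s <- psi / (1 - rb^2)^2
  (atanh(r_1c) - atanh(r_2c)) * sqrt((n - 3) / (2 * (1 - s)))
}

# Huber loss evaluated at fixed scale; minimized numerically to check IRLS.
huber_loss <- function(beta, X, y, c, sigma) {
  u <- (y - drop(X %*% beta)) / sigma
  rho <- ifelse(abs(u) <= c, u^2 / 2, c * abs(u) - c^2 / 2)
  sum(rho)
}

# Columnwise Pearson correlation between paired sample matrices (rows =
# observations) for fast simulation sweeps.
colwise_cor <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  colSums(Xc * Yc) / sqrt(colSums(Xc^2) * colSums(Yc^2))
}

# Small convenience: the default 94-institution, 5-year panel.
default_sim <- function(seed = 1) {
  generate_panel(default_params(seed = seed))
}
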
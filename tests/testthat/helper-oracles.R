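# Independent brute-force oracles used to validate the optimised
# implementations. These deliberately use direct enumeration and elementary
# formulas, not the package's code paths.

# Fisher two-tailed (point-probability): enumerate every table with the
# observed margins, computing point probabilities from binomial coefficients.
oracle_fisher_point <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c; N <- n1 + n2
  support <- max(0, k - n2):min(k, n1)
  probs <- choose(n1, support) * choose(n2, k - support) / choose(N, k)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Barnard two-tailed, pooled z ordering: plain dense-grid maximisation with
# no refinement step, written independently of the package internals.
oracle_barnard <- function(a, b, c, d, grid_n = 5000) {
  n1 <- a + b; n2 <- c + d
  tabs <- expand.grid(x1 = 0:n1, x2 = 0:n2)
  zstat <- function(x1, x2) {
    p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
    ifelse(v <= 0, 0, (p1 - p2) / sqrt(v))
  }
  z_obs <- zstat(a, c)
  ext <- abs(zstat(tabs$x1, tabs$x2)) >= abs(z_obs) - 1e-10
  best <- 0
  for (pi in seq(0.0005, 0.9995, length.out = grid_n)) {
    p <- sum(dbinom(tabs$x1[ext], n1, pi) * dbinom(tabs$x2[ext], n2, pi))
    if (p > best) best <- p
  }
  best
}

# Mann-Whitney exact two-tailed: literal enumeration of every assignment of
# the pooled observations to the first group, two-tailed by symmetric
# deviation of the rank sum from its null mean.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (N + 1) / 2
  dev_obs <- abs(sum(r[seq_len(n1)]) - mu)
  assignments <- utils::combn(N, n1)
  devs <- abs(apply(assignments, 2, function(idx) sum(r[idx])) - mu)
  mean(devs >= dev_obs - 1e-9)
}

# Shannon in bits by explicit term-by-term summation.
oracle_shannon_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts[counts > 0])
  s <- 0
  for (pi in p) s <- s - pi * log(pi, base = 2)
  s
}
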
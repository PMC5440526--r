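# Small-sample test battery for two-group comparisons: uncorrected Pearson
# chi-square, two-tailed exact Fisher (point-probability convention), the
# unconditional exact test of Barnard, pooled-variance t (from raw vectors or
# summary statistics), exact Mann-Whitney with mid-ranks, and the one-sample
# normal-theory binomial proportion test. Each returns an "mm_test" object
# with broom-style tidy()/glance() methods.

new_mm_test <- function(test, statistic, p_value, df = NA_real_,
                        exact = FALSE, inputs = list(), detail = NULL) {
  structure(
    list(test = test, statistic = unname(statistic),
         p_value = min(1, max(0, unname(p_value))), df = df, exact = exact,
         inputs = inputs, detail = detail),
    class = "mm_test"
  )
}

#' @export
print.mm_test <- function(x, ...) {
  cat(x$test, if (x$exact) "(exact)" else sprintf("(df = %g)", x$df), "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$detail)) cat(" ", x$detail, "\n")
  invisible(x)
}

#' Tidy a test result into a one-row tibble
#'
#' @param x An `mm_test` object.
#' @param ... Unused.
#' @return A tibble with columns `test`, `statistic`, `p_value`, `df`,
#'   `exact`.
#' @export
tidy.mm_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         df = x$df, exact = x$exact)
}

#' @rdname tidy.mm_test
#' @export
glance.mm_test <- function(x, ...) tidy(x)

#' Uncorrected Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square statistic without the continuity correction, one
#' degree of freedom. For a 2x2 table this statistic equals the square of the
#' pooled two-proportion z statistic. Used to compare detection proportions
#' between groups when counts are large enough.
#'
#' @param x A 2x2 table: matrix, data frame, or `c(a, b, c, d)` row-wise
#'   (rows = groups, columns = outcome yes/no).
#' @return An `mm_test` object.
#' @export
#' @examples
#' chisq_uncorrected(c(151, 184, 185, 96))
chisq_uncorrected <- function(x) {
  m <- as_2x2(x)
  if (any(rowSums(m) == 0)) abort("both row (group) sums must be positive")
  if (any(colSums(m) == 0)) {
    warn("a column sum is zero: proportions are equal by construction, p = 1")
    return(new_mm_test("chi-square (uncorrected)", 0, 1, df = 1,
                       inputs = list(table = m)))
  }
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  new_mm_test(
    "chi-square (uncorrected)", stat, pchisq(stat, df = 1, lower.tail = FALSE),
    df = 1, inputs = list(table = m)
  )
}

#' Two-tailed exact Fisher test for a 2x2 table
#'
#' Conditional exact test: with the margins fixed, the two-tailed p-value is
#' the sum of the hypergeometric point probabilities of every table no more
#' probable than the observed one (the point-probability convention, the
#' dominant definition). The doubling convention (twice the smaller one-sided
#' tail, capped at 1) is available for sensitivity analyses.
#'
#' @inheritParams chisq_uncorrected
#' @param method `"point"` (default) or `"doubling"`.
#' @return An `mm_test` object; the statistic is the sample odds ratio.
#' @export
#' @examples
#' fisher_exact_2x2(c(7, 3, 0, 5))
fisher_exact_2x2 <- function(x, method = c("point", "doubling")) {
  method <- arg_match(method)
  m <- as_2x2(x)
  a <- m[1, 1]
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ]); k <- sum(m[, 1])
  support <- max(0, k - n2):min(k, n1)
  probs <- dhyper(support, n1, n2, k)
  p_obs <- dhyper(a, n1, n2, k)
  p <- if (method == "point") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    min(1, 2 * min(lower, upper))
  }
  odds <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  new_mm_test("Fisher exact (two-tailed)", odds, p, exact = TRUE,
              inputs = list(table = m, method = method))
}

#' Two-tailed unconditional exact (Barnard) test for a 2x2 table
#'
#' Unconditional exact test for comparing two binomial proportions with very
#' small groups. The ordering statistic is the two-proportion z with pooled
#' variance, T = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with p the pooled
#' proportion (T = 0 where the variance vanishes). The p-value is the
#' supremum over the common nuisance success probability pi of the total
#' probability of all tables at least as extreme as the observed one
#' (|T| >= |T_obs|), computed on an `n_grid`-point grid over (0, 1) followed
#' by local refinement around the grid maximum.
#'
#' @inheritParams chisq_uncorrected
#' @param n_grid Number of nuisance-parameter grid points (default 2000,
#'   minimum 10).
#' @param statistic `"pooled"` (default) or `"unpooled"` Wald variance in the
#'   ordering statistic; the unpooled variant is provided for sensitivity
#'   analyses.
#' @return An `mm_test` object; the statistic is the observed `T`.
#' @export
#' @examples
#' barnard_exact_2x2(c(7, 3, 0, 5))
barnard_exact_2x2 <- function(x, n_grid = 2000,
                              statistic = c("pooled", "unpooled")) {
  statistic <- arg_match(statistic)
  if (!is.numeric(n_grid) || length(n_grid) != 1L || n_grid < 10) {
    abort("n_grid must be a single number >= 10")
  }
  m <- as_2x2(x)
  if (any(rowSums(m) == 0)) abort("both row (group) sums must be positive")
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  x1 <- 0:n1; x2 <- 0:n2
  p1 <- matrix(x1 / n1, n1 + 1L, n2 + 1L)
  p2 <- matrix(x2 / n2, n1 + 1L, n2 + 1L, byrow = TRUE)
  if (statistic == "pooled") {
    pp <- (p1 * n1 + p2 * n2) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  } else {
    v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
  }
  Tm <- (p1 - p2) / sqrt(v)
  Tm[v <= 0] <- 0 # both margins all-success or all-failure: no evidence
  T_obs <- Tm[m[1, 1] + 1L, m[2, 1] + 1L]
  extreme <- abs(Tm) >= abs(T_obs) - 1e-10
  idx <- which(extreme, arr.ind = TRUE)
  k1 <- x1[idx[, 1]]; k2 <- x2[idx[, 2]]
  tail_prob <- function(pi) {
    # total probability of the extreme region at nuisance value pi
    vapply(pi, function(p) sum(dbinom(k1, n1, p) * dbinom(k2, n2, p)),
           numeric(1))
  }
  grid <- seq_len(n_grid) / (n_grid + 1)
  vals <- colSums(
    outer(k1, grid, function(k, p) dbinom(k, n1, p)) *
      outer(k2, grid, function(k, p) dbinom(k, n2, p))
  )
  best <- which.max(vals)
  lo <- grid[max(1L, best - 1L)]; hi <- grid[min(n_grid, best + 1L)]
  refined <- optimize(tail_prob, c(lo, hi), maximum = TRUE)
  p <- max(vals[best], refined$objective)
  new_mm_test(
    "Barnard exact (two-tailed)", T_obs, p, exact = TRUE,
    inputs = list(table = m, n_grid = n_grid, statistic = statistic),
    detail = sprintf("nuisance maximum near pi = %.4f",
                     if (refined$objective >= vals[best]) refined$maximum
                     else grid[best])
  )
}

#' Two-tailed pooled-variance t test
#'
#' Student's unpaired t test with pooled variance, df = n1 + n2 - 2. Accepts
#' either raw vectors (`x`, `y`) or group summary statistics (mean, sd, n),
#' which makes published tables directly testable.
#'
#' @param x,y Optional raw data vectors.
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics, used when `x`
#'   and `y` are not given. `n1`, `n2` must be at least 2.
#' @return An `mm_test` object.
#' @export
#' @examples
#' pooled_t_test(mean1 = 1.8, sd1 = 1.5, n1 = 10, mean2 = 5.0, sd2 = 2.6, n2 = 5)
pooled_t_test <- function(x = NULL, y = NULL,
                          mean1 = NULL, sd1 = NULL, n1 = NULL,
                          mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) abort("supply both x and y, or summaries")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (is.null(mean1) || is.null(sd1) || is.null(n1) ||
        is.null(mean2) || is.null(sd2) || is.null(n2)) {
    abort("supply x and y, or all six summary statistics")
  }
  if (n1 < 2 || n2 < 2) abort("both groups need at least two observations")
  if (sd1 < 0 || sd2 < 0) abort("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  inputs <- list(mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2)
  if (sp2 == 0) {
    if (mean1 == mean2) {
      return(new_mm_test("pooled t (two-tailed)", 0, 1, df, inputs = inputs))
    }
    warn("zero variance in both groups with unequal means: p = 0")
    return(new_mm_test("pooled t (two-tailed)",
                       sign(mean1 - mean2) * Inf, 0, df, inputs = inputs))
  }
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  new_mm_test("pooled t (two-tailed)", tstat,
              2 * pt(-abs(tstat), df), df, inputs = inputs)
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' For small samples (`n1 + n2 <= exact_limit`) the p-value is exact: ties
#' are handled with mid-ranks and the full set of choose(n1+n2, n1) group
#' assignments is enumerated, counting assignments whose rank sum deviates
#' from its null mean at least as much as the observed one. Larger samples
#' use the normal approximation with the tie-corrected variance and a
#' continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_limit Maximum combined sample size for exhaustive enumeration
#'   (default 12).
#' @return An `mm_test` object; the statistic is the Mann-Whitney U of the
#'   first sample.
#' @export
mann_whitney_test <- function(x, y, exact_limit = 12) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("both samples must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y)) # mid-ranks for ties
  W_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  U_obs <- W_obs - n1 * (n1 + 1) / 2
  inputs <- list(x = x, y = y)
  if (N <= exact_limit) {
    sets <- utils::combn(N, n1)
    W_all <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
    return(new_mm_test("Mann-Whitney (exact, two-tailed)", U_obs, p,
                       exact = TRUE, inputs = inputs))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) {
    return(new_mm_test("Mann-Whitney (normal approx., two-tailed)", U_obs, 1,
                       inputs = inputs))
  }
  z <- (abs(W_obs - mu) - 0.5) / sqrt(sigma2)
  new_mm_test("Mann-Whitney (normal approx., two-tailed)", U_obs,
              2 * pnorm(-max(0, z)), inputs = inputs)
}

#' One-sample binomial proportion test, normal-theory method
#'
#' z = (k/n - p0) / sqrt(p0 (1 - p0) / n), two-tailed normal p-value.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param p0 Null success probability, strictly between 0 and 1.
#' @return An `mm_test` object.
#' @export
prop_test_one_sample <- function(k, n, p0) {
  if (n <= 0) abort("n must be positive")
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly between 0 and 1")
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  new_mm_test("one-sample proportion (normal theory)", z, 2 * pnorm(-abs(z)),
              inputs = list(k = k, n = n, p0 = p0))
}

# Test-selection policy for 2x2 detection tables, mirroring common practice
# with very small cohorts: exact unconditional test when both groups are tiny
# (per-sample presence), exact Fisher when an expected cell is small,
# otherwise the uncorrected chi-square.
select_2x2_test <- function(m, per_sample = FALSE, barnard_max_n = 10,
                            fisher_min_expected = 5) {
  m <- as_2x2(m)
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  if (per_sample && n1 <= barnard_max_n && n2 <= barnard_max_n) {
    return("barnard")
  }
  if (any(colSums(m) == 0)) return("fisher")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  if (min(E) < fisher_min_expected) "fisher" else "chisq"
}

run_2x2_test <- function(m, choice) {
  switch(choice,
    barnard = barnard_exact_2x2(m),
    fisher = fisher_exact_2x2(m),
    chisq = chisq_uncorrected(m),
    abort(sprintf("unknown test choice %s", dQuote(choice)))
  )
}
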
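# The small-sample test battery.

test_that("uncorrected chi-square reproduces published 2x2 comparisons", {
  expect_equal(chisq_uncorrected(c(151, 184, 185, 96))$p_value, 2.544205e-07,
               tolerance = 1e-6)
  expect_equal(chisq_uncorrected(c(56, 279, 25, 256))$p_value, 0.004230592,
               tolerance = 1e-6)
  flat <- chisq_uncorrected(c(5, 5, 5, 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("chi-square equals the squared pooled two-proportion z", {
  withr::with_seed(12, {
    for (i in 1:25) {
      m <- c(rbinom(2, 30, 0.4) + 1, rbinom(2, 25, 0.5) + 1)
      a <- m[1]; b <- m[2]; c_ <- m[3]; d <- m[4]
      n1 <- a + b; n2 <- c_ + d
      pp <- (a + c_) / (n1 + n2)
      z <- (a / n1 - c_ / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      expect_equal(chisq_uncorrected(m)$statistic, z^2, tolerance = 1e-10)
    }
  })
})

test_that("chi-square agrees with the standard library implementation", {
  withr::with_seed(23, {
    for (i in 1:10) {
      m <- matrix(rbinom(4, 50, 0.4) + 1, 2)
      ref <- stats::chisq.test(m, correct = FALSE)
      mine <- chisq_uncorrected(m)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("degenerate chi-square tables give p = 1 with a warning", {
  expect_warning(res <- chisq_uncorrected(c(0, 10, 0, 5)), "column")
  expect_equal(res$p_value, 1)
  expect_error(chisq_uncorrected(c(0, 0, 3, 2)), "row")
})

test_that("Fisher point-probability p-values match enumeration cases", {
  expect_equal(fisher_exact_2x2(c(0, 10, 0, 5))$p_value, 1)
  expect_equal(fisher_exact_2x2(c(7, 3, 0, 5))$p_value, 0.02564103,
               tolerance = 1e-6)
  expect_gt(fisher_exact_2x2(c(1, 588, 1, 485))$p_value, 0.99)
})

test_that("Fisher agrees with the standard library and the doubling option", {
  withr::with_seed(5, {
    for (i in 1:20) {
      m <- matrix(rbinom(4, 12, 0.5), 2)
      if (any(rowSums(m) == 0)) next
      expect_equal(fisher_exact_2x2(m)$p_value,
                   stats::fisher.test(m)$p.value, tolerance = 1e-9)
    }
  })
  # doubling convention: twice the smaller tail, capped at one
  m <- c(7, 3, 0, 5)
  point <- fisher_exact_2x2(m)$p_value
  doubled <- fisher_exact_2x2(m, method = "doubling")$p_value
  expect_gte(doubled, point)
})

test_that("Barnard reproduces its enumeration oracle and edge cases", {
  for (tab in list(c(7, 3, 0, 5), c(9, 1, 1, 4), c(3, 2, 1, 4))) {
    expect_equal(barnard_exact_2x2(tab)$p_value,
                 oracle_barnard(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-4)
  }
  expect_equal(barnard_exact_2x2(c(2, 2, 2, 2))$p_value, 1)
  expect_error(barnard_exact_2x2(c(1, 1, 1, 1), n_grid = 5), "n_grid")
  # unpooled-variance ordering is a different test and may disagree
  expect_true(is.numeric(
    barnard_exact_2x2(c(7, 3, 0, 5), statistic = "unpooled")$p_value
  ))
})

test_that("all two-tailed 2x2 tests are invariant under group swap", {
  withr::with_seed(42, {
    for (i in 1:8) {
      m <- c(rbinom(1, 10, 0.6), rbinom(1, 10, 0.4),
             rbinom(1, 5, 0.4), rbinom(1, 5, 0.6)) + c(1, 1, 0, 1)
      swapped <- m[c(3, 4, 1, 2)]
      expect_equal(chisq_uncorrected(m)$p_value,
                   chisq_uncorrected(swapped)$p_value, tolerance = 1e-12)
      expect_equal(fisher_exact_2x2(m)$p_value,
                   fisher_exact_2x2(swapped)$p_value, tolerance = 1e-9)
      expect_equal(barnard_exact_2x2(m, n_grid = 200)$p_value,
                   barnard_exact_2x2(swapped, n_grid = 200)$p_value,
                   tolerance = 1e-6)
    }
  })
})

test_that("pooled t from summaries reproduces published comparisons", {
  expect_equal(
    pooled_t_test(mean1 = 1.8, sd1 = 1.5, n1 = 10,
                  mean2 = 5.0, sd2 = 2.6, n2 = 5)$p_value,
    0.009066603, tolerance = 1e-6
  )
  expect_equal(
    pooled_t_test(mean1 = 3.2, sd1 = 0.8, n1 = 10,
                  mean2 = 3.8, sd2 = 0.8, n2 = 5)$p_value,
    0.1940956, tolerance = 1e-6
  )
  expect_equal(
    pooled_t_test(mean1 = 2, sd1 = 1, n1 = 5, mean2 = 2, sd2 = 3, n2 = 5)$p_value,
    1
  )
})

test_that("pooled t from raw vectors equals t from their summaries", {
  withr::with_seed(9, {
    x <- rnorm(8, 1); y <- rnorm(6, 2)
  })
  from_raw <- pooled_t_test(x = x, y = y)
  from_sum <- pooled_t_test(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                            mean2 = mean(y), sd2 = sd(y), n2 = length(y))
  expect_equal(from_raw$statistic, from_sum$statistic, tolerance = 1e-12)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(from_raw$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate zero-variance t inputs are handled explicitly", {
  expect_warning(
    res <- pooled_t_test(mean1 = 1, sd1 = 0, n1 = 5, mean2 = 2, sd2 = 0, n2 = 5),
    "zero variance"
  )
  expect_equal(res$p_value, 0)
  expect_error(pooled_t_test(mean1 = 1, sd1 = 1, n1 = 1,
                             mean2 = 2, sd2 = 1, n2 = 5), "two observations")
})

test_that("exact Mann-Whitney equals full permutation enumeration", {
  cases <- list(
    list(x = c(1.2, 3.4, 2.2), y = c(5.5, 4.4, 6.6)),
    list(x = c(1, 2, 2), y = c(2, 3, 4)), # ties across groups
    list(x = c(10, 12, 9, 14), y = c(11, 8, 13))
  )
  for (cs in cases) {
    expect_equal(mann_whitney_test(cs$x, cs$y)$p_value,
                 oracle_mw_exact(cs$x, cs$y))
  }
  # identical multisets split evenly: no evidence at all
  expect_equal(mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney_test(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with the standard library without ties", {
  withr::with_seed(14, {
    x <- rnorm(5); y <- rnorm(6)
  })
  expect_equal(mann_whitney_test(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("normal approximation tracks the exact Mann-Whitney p", {
  withr::with_seed(27, {
    x <- round(rnorm(7, 0, 2), 1); y <- round(rnorm(7, 1, 2), 1)
  })
  exact <- mann_whitney_test(x, y, exact_limit = 14)$p_value
  approx <- mann_whitney_test(x, y, exact_limit = 2)$p_value
  expect_lt(abs(exact - approx), 0.01)
})

test_that("one-sample proportion test follows the normal-theory closed form", {
  expect_equal(prop_test_one_sample(50, 100, 0.5)$p_value, 1)
  expect_equal(prop_test_one_sample(30, 100, 0.3)$p_value, 1)
  res <- prop_test_one_sample(90, 100, 0.5)
  expect_equal(res$statistic, 8)
  expect_equal(res$p_value, 2 * pnorm(-8))
  expect_error(prop_test_one_sample(5, 0, 0.5), "positive")
  expect_error(prop_test_one_sample(5, 10, 1), "p0")
})

test_that("test results tidy into one-row tibbles", {
  td <- tidy(chisq_uncorrected(c(5, 5, 2, 8)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c("test", "statistic", "p_value", "df", "exact"))
  expect_equal(glance(barnard_exact_2x2(c(2, 2, 2, 2)))$exact, TRUE)
})
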
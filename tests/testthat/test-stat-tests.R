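test_that("Shapiro-Wilk flags heavy-tailed data and accepts its bounds", {
  set.seed(101)
  heavy <- c(rnorm(40), rnorm(10, sd = 8))  # contaminated mixture, n = 50
  res <- shapiro_wilk(heavy)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$statistic, 0)
  expect_lte(res$statistic, 1)
  # equally spaced points are close to the symmetric-data maximum of W
  even <- seq_len(20)
  expect_gt(shapiro_wilk(even)$statistic, 0.95)
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("variance F-test matches its contract and stats::var.test", {
  x <- c(1, 2, 3, 4, 5)
  res <- variance_f_test(x, x)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1)
  set.seed(7)
  a <- rnorm(30, sd = 2)
  b <- rnorm(25, sd = 1)
  fwd <- variance_f_test(a, b)
  rev <- variance_f_test(b, a)
  expect_equal(fwd$statistic, 1 / rev$statistic, tolerance = 1e-12)
  # the swapped p-value is computed from the opposite F tail, so agreement
  # is limited by the tail-probability precision, not exact arithmetic
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-8)
  ref <- var.test(a, b)
  expect_equal(fwd$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fwd$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(fwd$df, c(29L, 24L))
  expect_error(variance_f_test(rep(1, 5), a), "zero variance")
})

test_that("an SD contrast like 0.27 vs 0.15 at n = 94 is decisively rejected", {
  set.seed(2024)
  x <- rnorm(94, sd = 0.27)
  y <- rnorm(94, sd = 0.15)
  expect_lt(variance_f_test(x, y)$p_value, 0.001)
})

test_that("Spearman rho handles monotone pairs and matches cor.test", {
  x <- c(0.3, 1.2, 2.5, 3.1, 7.7)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x^3)$rho, -1)
  set.seed(13)
  a <- rnorm(40)
  b <- a + rnorm(40)
  expect_equal(spearman_correlation(a, b)$rho,
               unname(cor.test(a, b, method = "spearman")$estimate),
               tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 1:4), "equal length")
})

test_that("Spearman equals the brute-force rank formula, including ties", {
  x8 <- c(1, 2, 2, 3, 5, 5, 5, 9)
  y8 <- c(4, 1, 7, 7, 2, 8, 3, 6)
  expect_equal(spearman_correlation(x8, y8)$rho,
               bruteforce_spearman(x8, y8), tolerance = 1e-12)
  set.seed(99)
  for (n in 3:12) {
    for (rep in 1:20) {
      x <- sample(1:6, n, replace = TRUE) + runif(n) * (rep %% 2)
      y <- sample(1:6, n, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      expect_equal(spearman_correlation(x, y)$rho, bruteforce_spearman(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("Spearman p-value follows the t approximation on n - 2 df", {
  set.seed(5)
  x <- rnorm(25)
  y <- x + rnorm(25, sd = 2)
  res <- spearman_correlation(x, y)
  tstat <- res$rho * sqrt((res$n - 2) / (1 - res$rho^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), res$n - 2), tolerance = 1e-12)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("Fisher z comparison matches the textbook formula", {
  same <- fisher_z_compare(0.5, 94, 0.5, 94)
  expect_identical(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ab <- fisher_z_compare(0.78, 94, 0.67, 94)
  expect_equal(ab$statistic, 1.582648494360, tolerance = 1e-10)
  expect_equal(ab$p_value, 0.113501603829, tolerance = 1e-9)
  ba <- fisher_z_compare(0.67, 94, 0.78, 94)
  expect_equal(ba$statistic, -ab$statistic, tolerance = 1e-12)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    r1 <- runif(1, -0.95, 0.95)
    r2 <- runif(1, -0.95, 0.95)
    n1 <- sample(5:500, 1)
    n2 <- sample(5:500, 1)
    expect_equal(fisher_z_compare(r1, n1, r2, n2)$statistic,
                 oracle_fisher_z(r1, n1, r2, n2), tolerance = 1e-10)
  }
  expect_error(fisher_z_compare(1, 10, 0.5, 10), "infinite z")
  expect_error(fisher_z_compare(0.5, 3, 0.5, 10), "exceed 3")
})

test_that("Steiger's dependent-correlation test matches its formula", {
  expect_equal(steiger_compare_dependent(0.5, 0.5, 0.3, 94)$statistic, 0)
  st <- steiger_compare_dependent(0.6, 0.4, 0.5, 94)
  expect_equal(st$statistic, 2.325420829803, tolerance = 1e-10)
  expect_equal(st$p_value, 0.020049468746, tolerance = 1e-9)
  set.seed(31)
  n_checked <- 0
  while (n_checked < 50) {
    r1 <- runif(1, -0.8, 0.8)
    r2 <- runif(1, -0.8, 0.8)
    r12 <- runif(1, -0.8, 0.8)
    R <- matrix(c(1, r12, r1, r12, 1, r2, r1, r2, 1), 3)
    if (det(R) <= 0) next
    n_checked <- n_checked + 1
    expect_equal(steiger_compare_dependent(r1, r2, r12, 50)$statistic,
                 oracle_steiger_z(r1, r2, r12, 50), tolerance = 1e-10)
  }
  # stronger dependence sharpens the contrast between unequal correlations
  z_low <- abs(steiger_compare_dependent(0.6, 0.3, 0.0, 94)$statistic)
  z_high <- abs(steiger_compare_dependent(0.6, 0.3, 0.8, 94)$statistic)
  expect_gt(z_high, z_low)
  expect_error(steiger_compare_dependent(0.9, -0.9, 0.9, 94), "infeasible")
})

test_that("Fisher z comparison holds its type-I error under the null", {
  # two independent samples with the same population correlation
  set.seed(515)
  n <- 100
  reps <- 10000
  rho <- 0.3
  sim_r <- function() {
    X <- matrix(rnorm(n * reps), n)
    Y <- rho * X + sqrt(1 - rho^2) * matrix(rnorm(n * reps), n)
    colwise_cor(X, Y)
  }
  r1 <- sim_r()
  r2 <- sim_r()
  z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  # same statistic the package computes, vectorized for speed
  expect_equal(fisher_z_compare(r1[1], n, r2[1], n)$statistic, z[1],
               tolerance = 1e-12)
  reject <- mean(2 * pnorm(-abs(z)) < 0.05)
  expect_gt(reject, 0.04)
  expect_lt(reject, 0.06)
})
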
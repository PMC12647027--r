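new_test_result <- function(test_name, statistic, df, p_value,
                            tails = "two-sided", ...) {
  structure(
    list(test_name = test_name, statistic = statistic, df = df,
         p_value = p_value, tails = tails, ...),
    class = "cawi_test_result"
  )
}

#' @export
print.cawi_test_result <- function(x, ...) {
  df_str <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g (%s)\n",
              x$test_name, x$statistic, df_str, x$p_value, x$tails))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Gatekeeping normality check used to decide between parametric and
#' rank-based methods; delegates the W statistic and Royston p-value to
#' [stats::shapiro.test()].
#'
#' @param values Numeric sample, 3 <= n <= 5000, non-constant.
#' @return A `cawi_test_result` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", n, call. = FALSE)
  }
  if (sd(values) == 0) {
    stop("undefined W: sample has zero variance", call. = FALSE)
  }
  st <- shapiro.test(values)
  new_test_result("Shapiro-Wilk W", unname(st$statistic), n, st$p.value)
}

#' Two-sided variance-ratio F-test
#'
#' Compares the dispersion of two samples via `F = var(x) / var(y)` with
#' `(n_x - 1, n_y - 1)` degrees of freedom; the two-sided p-value is
#' `2 * min(P(F <= f), P(F >= f))`, capped at 1. Used to test whether the
#' complexity-adjusted index is less dispersed across institutions than the
#' raw generation rate.
#'
#' @param x,y Numeric samples, each with >= 2 points and positive variance.
#' @return A `cawi_test_result` with fields `statistic` (F), `df` (length-2),
#'   `p_value`.
#' @export
variance_f_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples need >= 2 observations", call. = FALSE)
  }
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 || vy == 0) {
    stop("zero variance in a sample: F statistic undefined", call. = FALSE)
  }
  f <- vx / vy
  df <- c(length(x) - 1L, length(y) - 1L)
  lower <- pf(f, df[1], df[2])
  p <- min(1, 2 * min(lower, 1 - lower))
  new_test_result("variance F-test", f, df, p)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' The Pearson correlation of average-ranked data (ties receive average
#' ranks), with a p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A `cawi_correlation` list: `rho`, `n`, `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop("Spearman correlation needs n >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined rho: constant input vector", call. = FALSE)
  }
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, n = n, p_value = p),
            class = "cawi_correlation")
}

#' @export
print.cawi_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.4g)\n",
              x$rho, x$n, x$p_value))
  invisible(x)
}

#' Fisher z-test comparing two correlation coefficients
#'
#' Applies the variance-stabilizing transform `z = atanh(r)` to each
#' coefficient and tests their difference on independent samples:
#' `Z = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`, two-sided p from the
#' standard normal. When the two correlations are measured on the same
#' subjects this independent-samples form is conservative in spirit only;
#' see [steiger_compare_dependent()] for the dependent-correlations version.
#'
#' @param r1,r2 Correlation coefficients, |r| < 1.
#' @param n1,n2 Sample sizes, each > 3.
#' @return A `cawi_test_result` with the Z statistic and two-sided p-value.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("infinite z: |r| must be < 1", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) {
    stop("sample sizes must exceed 3", call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  new_test_result("Fisher z comparison", z, NA_real_,
                  2 * pnorm(-abs(z)))
}

#' Steiger's test for two dependent, overlapping correlations
#'
#' Compares `cor(X1, Y)` with `cor(X2, Y)` measured on one sample of size
#' `n`, accounting for the correlation `r12 = cor(X1, X2)` between the two
#' predictors (Steiger, 1980, Case A with pooled r-bar):
#' \deqn{Z = (z_1 - z_2) \sqrt{\frac{n - 3}{2 (1 - s)}}}
#' where `z_i = atanh(r_ic)` and `s` is the estimated covariance of the two
#' transformed coefficients. Appropriate here because both waste indicators
#' are measured on the same institutions.
#'
#' @param r_1c,r_2c The two correlations with the shared variable, |r| < 1.
#' @param r_12 Correlation between the two non-shared variables, |r| < 1.
#' @param n Sample size, > 4.
#' @return A `cawi_test_result` with the Z statistic and two-sided p-value.
#' @export
steiger_compare_dependent <- function(r_1c, r_2c, r_12, n) {
  if (any(abs(c(r_1c, r_2c, r_12)) >= 1)) {
    stop("infinite z: all |r| must be < 1", call. = FALSE)
  }
  if (n <= 4) {
    stop("sample size must exceed 4", call. = FALSE)
  }
  R <- matrix(c(1, r_12, r_1c,
                r_12, 1, r_2c,
                r_1c, r_2c, 1), nrow = 3)
  if (det(R) <= 0) {
    stop("infeasible input: the implied correlation matrix is not ",
         "positive definite", call. = FALSE)
  }
  rbar <- (r_1c + r_2c) / 2
  psi <- r_12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_12^2)
  s <- psi / (1 - rbar^2)^2
  z <- (atanh(r_1c) - atanh(r_2c)) * sqrt((n - 3) / (2 * (1 - s)))
  new_test_result("Steiger dependent-correlation comparison", z, NA_real_,
                  2 * pnorm(-abs(z)))
}
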
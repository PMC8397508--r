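## Agreement and regression statistics.
##
## The intraclass correlation implemented here is the two-way model with
## absolute agreement — McGraw & Wong's ICC(A,1) (single measures) and
## ICC(A,k) (average measures), the variant SPSS reports as "two-way
## mixed / absolute agreement".  It is the appropriate statistic for
## comparing an algorithm's TIV estimates against a human rater's, because
## absolute agreement penalizes systematic bias between raters, not just
## loss of correlation.

#' Two-way absolute-agreement intraclass correlation
#'
#' Decomposes a complete `n` subjects x `k` raters matrix by two-way ANOVA
#' without replication into between-subject (MSR), between-rater (MSC) and
#' residual (MSE) mean squares, and reports
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#' \deqn{ICC(A,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}}
#' with the F test of "true value 0" (`F = MSR/MSE`, `df1 = n-1`,
#' `df2 = (n-1)(k-1)`) and confidence intervals from the McGraw–Wong
#' absolute-agreement formulas (the single-measures interval uses a
#' Satterthwaite-approximated denominator df; the average-measures interval
#' is its Spearman–Brown transform).
#'
#' @param ratings Numeric matrix or data.frame, subjects in rows and raters
#'   in columns; complete (no missing cells), `n >= 2`, `k >= 2`.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return An object of class `icc_result`: `icc_single`, `icc_average`,
#'   `ci95_single`, `ci95_average`, `f_value`, `df1`, `df2`, `p_value`,
#'   `ms` (the three mean squares), `n`, `k`, `conf_level`.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stop("`ratings` must be numeric")
  if (any(is.na(x))) stop("`ratings` must be complete (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (conf_level <= 0 || conf_level >= 1) stop("`conf_level` must be in (0, 1)")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((x - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- max(sse, 0) / ((n - 1) * (k - 1))
  if (msr <= 0 && mse <= 0)
    stop("constant ratings matrix: the ICC is undefined")
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # perfect agreement: all variance is between subjects
    icc1 <- icck <- 1
    fv <- Inf; p <- 0
    ci1 <- cik <- c(1, 1)
  } else if (mse == 0) {
    # raters differ only by systematic offsets: no residual disagreement,
    # but absolute agreement is still penalized by the rater variance
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    icck <- (msr - mse) / (msr + (msc - mse) / n)
    fv <- Inf; p <- 0
    # limits of the general interval as MSE -> 0 (Satterthwaite df -> k-1)
    f_up <- qf(1 - alpha / 2, n - 1, k - 1)
    f_lo <- qf(1 - alpha / 2, k - 1, n - 1)
    lower <- n * msr / (f_up * k * msc + n * msr)
    upper <- n * f_lo * msr / (k * msc + n * f_lo * msr)
    ci1 <- c(lower, upper)
    sb <- function(r) k * r / (1 + (k - 1) * r)
    cik <- sb(ci1)
  } else {
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    icck <- (msr - mse) / (msr + (msc - mse) / n)
    fv <- msr / mse
    p <- pf(fv, df1, df2, lower.tail = FALSE)
    # Satterthwaite df for the ICC(A,1) interval
    a <- (k * icc1) / (n * (1 - icc1))
    b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_up <- qf(1 - alpha / 2, n - 1, v)
    f_lo <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_up * mse) /
      (f_up * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_lo * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_lo * msr)
    ci1 <- c(lower, upper)
    sb <- function(r) k * r / (1 + (k - 1) * r)  # Spearman-Brown
    cik <- sb(ci1)
  }
  structure(list(icc_single = icc1, icc_average = icck,
                 ci95_single = ci1, ci95_average = cik,
                 f_value = fv, df1 = df1, df2 = df2, p_value = p,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 n = n, k = k, conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("Intraclass correlation (two-way, absolute agreement), n = %d, k = %d\n",
              x$n, x$k))
  cat(sprintf("  single measures  ICC(A,1) = %.3f  %g%% CI [%.3f, %.3f]\n",
              x$icc_single, 100 * x$conf_level, x$ci95_single[1],
              x$ci95_single[2]))
  cat(sprintf("  average measures ICC(A,%d) = %.3f  %g%% CI [%.3f, %.3f]\n",
              x$k, x$icc_average, 100 * x$conf_level, x$ci95_average[1],
              x$ci95_average[2]))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df1, x$df2, x$f_value,
              x$p_value))
  invisible(x)
}

#' Simple linear regression with R²
#'
#' Ordinary least squares of `y` on `x`, used for phantom linearity checks
#' (estimated TIV against organoid count).  A constant response yields a
#' zero slope and `r_squared = 0` by convention.
#'
#' @param x Predictor values (not constant, `n >= 3`).
#' @param y Response values.
#' @return An object of class `mpi_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided, slope = 0), `n`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` differ in length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (length(unique(x)) < 2L) stop("`x` is constant; regression is undefined")
  fit <- lm(y ~ x)
  co <- coef(fit)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- 0
    p <- NA_real_
  } else {
    sf <- suppressWarnings(summary(fit))
    r2 <- sf$r.squared
    p <- sf$coefficients["x", "Pr(>|t|)"]
  }
  structure(list(slope = unname(co[["x"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r_squared = r2, p_value = p, n = length(x)),
            class = "mpi_regression")
}

#' @export
print.mpi_regression <- function(x, ...) {
  cat(sprintf("linear regression (n = %d): y = %.6g x %+.6g, R^2 = %.4f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}
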
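# Independent oracles used across the suite.

# Exact 1-D k-means optimum by enumerating contiguous partitions of the
# sorted data (for squared loss the optimal 1-D clusters are contiguous in
# sorted order, so enumerating the choose(n-1, k-1) cut placements is
# exhaustive).
oracle_wcss_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    w <- 0
    for (i in seq_len(k)) {
      seg <- x[(b[i] + 1):b[i + 1]]
      w <- w + sum((seg - mean(seg))^2)
    }
    if (w < best) best <- w
  }
  best
}

# Reference route to the two-way absolute-agreement ICC: mean squares from
# a two-way ANOVA fitted with lm()/anova() (rather than direct sums of
# squares), then the McGraw-Wong formulas.
oracle_icc <- function(m, conf_level = 0.95) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  a <- anova(lm(y ~ subj + rater, data = d))
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  alpha <- 1 - conf_level
  aa <- (k * icc1) / (n * (1 - icc1))
  bb <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_up <- qf(1 - alpha / 2, n - 1, v)
  f_lo <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_up * mse) /
    (f_up * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_lo * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_lo * msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  list(icc_single = icc1, icc_average = icck,
       ci_single = c(lo, hi), ci_average = sb(c(lo, hi)),
       f_value = msr / mse)
}

# Random complete ratings matrix with subject structure plus rater noise.
random_ratings <- function(n, k, sd_rater = 0.8) {
  subj <- rnorm(n, 5, 2)
  matrix(rep(subj, k) + rnorm(n * k, 0, sd_rater), n, k)
}
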
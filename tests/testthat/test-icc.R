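# Two-way absolute-agreement ICC and linear regression.

# Values computed with an independent reference implementation of the
# McGraw-Wong absolute-agreement ICC (pingouin 0.6.1, ICC(A,1)/ICC(A,k));
# confidence bounds are as printed by the reference (2 decimals).
ref_m6 <- matrix(c(4.1, 4.3, 5.0, 4.6, 2.2, 2.9, 7.7, 7.1, 6.5, 6.9,
                   3.3, 3.0), ncol = 2, byrow = TRUE)
ref_m6_vals <- list(icc_single = 0.9710828365512946,
                    icc_average = 0.9853293007719045,
                    ci_single = c(0.81, 1.00), ci_average = c(0.89, 1.00),
                    f_value = 56.9692307692309, df1 = 5L, df2 = 5L,
                    p_value = 0.00020841570370482408)
ref_m15 <- matrix(c(5.002, 4.373, 4.452, 2.837, 4.091, 2.234, 5.120, 7.033,
                    4.016, 4.608, 5.980, 5.068, 5.211, 3.113, 4.941, 7.099,
                    2.312, 3.618, 1.198, 2.332, 1.317, 4.618, 2.465, 5.594,
                    5.314, 3.646, -0.034, 3.984, 4.903, 6.314),
                  ncol = 2, byrow = TRUE)
ref_m15_vals <- list(icc_single = 0.27600332735169636,
                     icc_average = 0.4326059680808707,
                     ci_single = c(-0.22, 0.67), ci_average = c(-0.57, 0.80),
                     f_value = 1.7963771528745847, df1 = 14L, df2 = 14L,
                     p_value = 0.14251492176814745)

test_that("frozen reference matrices reproduce the McGraw-Wong values", {
  for (case in list(list(ref_m6, ref_m6_vals), list(ref_m15, ref_m15_vals))) {
    r <- icc_absolute_agreement(case[[1]])
    v <- case[[2]]
    expect_equal(r$icc_single, v$icc_single, tolerance = 1e-10)
    expect_equal(r$icc_average, v$icc_average, tolerance = 1e-10)
    expect_equal(r$f_value, v$f_value, tolerance = 1e-10)
    expect_identical(r$df1, v$df1)
    expect_identical(r$df2, v$df2)
    expect_equal(r$p_value, v$p_value, tolerance = 1e-10)
    # reference bounds are printed at 2 decimals
    expect_lt(max(abs(r$ci95_single - v$ci_single)), 0.005)
    expect_lt(max(abs(r$ci95_average - v$ci_average)), 0.005)
  }
})

test_that("identical rater columns give perfect agreement", {
  m <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  r <- icc_absolute_agreement(m)
  expect_equal(r$icc_single, 1)
  expect_equal(r$icc_average, 1)
  expect_equal(r$p_value, 0)
})

test_that("a 15x2 matrix reports df1 = 14 and df2 = 14", {
  set.seed(21)
  r <- icc_absolute_agreement(random_ratings(15, 2))
  expect_identical(r$df1, 14L)
  expect_identical(r$df2, 14L)
})

test_that("random matrices agree with the ANOVA-route reference to 1e-8", {
  set.seed(77)
  for (i in 1:25) {
    for (n in c(6, 15)) {
      m <- random_ratings(n, 2, sd_rater = runif(1, 0.2, 2))
      mine <- icc_absolute_agreement(m)
      ref <- oracle_icc(m)
      expect_equal(mine$icc_single, ref$icc_single, tolerance = 1e-8)
      expect_equal(mine$icc_average, ref$icc_average, tolerance = 1e-8)
      expect_equal(mine$ci95_single, ref$ci_single, tolerance = 1e-8)
      expect_equal(mine$ci95_average, ref$ci_average, tolerance = 1e-8)
      expect_equal(mine$f_value, ref$f_value, tolerance = 1e-8)
    }
  }
})

test_that("a constant offset on one rater breaks absolute agreement", {
  m <- cbind(c(2, 4, 9, 6, 3), c(2, 4, 9, 6, 3))
  m2 <- m
  m2[, 2] <- m2[, 2] + 1.5
  r <- icc_absolute_agreement(m2)
  expect_lt(r$icc_single, 1)
  expect_lt(r$icc_average, 1)
})

test_that("ICC is invariant under subject reordering and common affine maps", {
  set.seed(13)
  m <- random_ratings(10, 3)
  r0 <- icc_absolute_agreement(m)
  r1 <- icc_absolute_agreement(m[sample(10), ])
  r2 <- icc_absolute_agreement(m * 3.2 - 40)
  expect_equal(r0$icc_single, r1$icc_single, tolerance = 1e-12)
  expect_equal(r0$icc_single, r2$icc_single, tolerance = 1e-9)
  expect_equal(r0$ci95_average, r2$ci95_average, tolerance = 1e-9)
})

test_that("average measures dominate single measures when positive", {
  set.seed(31)
  for (i in 1:20) {
    r <- icc_absolute_agreement(random_ratings(8, 2, sd_rater = runif(1, 0.5, 3)))
    if (r$icc_single > 0) expect_gte(r$icc_average, r$icc_single)
  }
})

test_that("degenerate ratings are rejected", {
  expect_error(icc_absolute_agreement(matrix(5, 4, 2)), "constant")
  expect_error(icc_absolute_agreement(matrix(1:4, 4, 1)), "2 subjects and 2")
  m <- cbind(c(1, NA, 3), c(1, 2, 3))
  expect_error(icc_absolute_agreement(m), "complete")
})

test_that("linear regression matches the closed-form normal equations", {
  x <- c(0, 25, 50, 100, 200, 400)
  y <- c(0.1, 0.9, 1.4, 3.2, 6.1, 12.4)
  r <- linear_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(r$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(r$intercept, mean(y) - r$slope * mean(x), tolerance = 1e-12)
  expect_equal(r$r_squared, sxy^2 / (sxx * sum((y - mean(y))^2)),
               tolerance = 1e-12)
})

test_that("regression edge cases follow the stated conventions", {
  expect_equal(linear_regression(1:5, 2 * (1:5) + 3)$r_squared, 1)
  r <- linear_regression(1:5, rep(4, 5))
  expect_equal(r$slope, 0)
  expect_equal(r$r_squared, 0)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
})
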
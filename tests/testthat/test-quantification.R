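# Fiducial arithmetic, standard curve, TIV estimation.

test_that("fiducial iron mass follows fraction x stock x volume", {
  expect_identical(fiducial_iron_mass(0.40, 5.5, 1), 2.2)
  expect_identical(fiducial_iron_mass(0.10, 5.5, 1), 0.55)
  expect_identical(fiducial_iron_mass(0.20, 5.5, 1), 1.1)
  sp <- fiducial_spec("f", c(1, 1, 1), 0.4)
  expect_identical(fiducial_iron_mass(sp), 2.2)
  expect_error(fiducial_iron_mass(1.5), "\\(0, 1\\]")
  expect_error(fiducial_iron_mass(0.4, -5, 1), "> 0")
})

test_that("origin-mode curve on proportional points is exact", {
  cv <- fit_standard_curve(c(100, 200, 400), c(0.55, 1.1, 2.2),
                           mode = "origin")
  expect_equal(cv$slope, 0.0055, tolerance = 1e-12)
  expect_identical(cv$intercept, 0)
  expect_equal(cv$r_squared, 1)
  # closed-form origin OLS: sum(xy)/sum(x^2)
  x <- c(120, 310, 480); y <- c(0.5, 1.4, 2.0)
  cv2 <- fit_standard_curve(x, y, mode = "origin")
  expect_equal(cv2$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
})

test_that("two distinct points in intercept mode fit perfectly", {
  cv <- fit_standard_curve(c(100, 300), c(0.6, 2.0), mode = "intercept")
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$slope * 100 + cv$intercept, 0.6, tolerance = 1e-12)
})

test_that("degenerate or inverted calibrations are rejected", {
  expect_error(fit_standard_curve(c(100, 100), c(1, 2)), "distinct")
  expect_error(fit_standard_curve(numeric(0), numeric(0), mode = "origin"),
               "at least")
  expect_error(fit_standard_curve(c(100, 200), c(2, 1), mode = "intercept"),
               "slope")
})

test_that("noise-free fiducial renders calibrate to 1/signal_per_ug", {
  sums <- vapply(c(0.55, 1.1, 2.2), function(iron) {
    cfg <- quiet_config(grid = c(16L, 24L, 24L),
                        sources = list(iron_source(c(8, 12, 12), iron,
                                                   "fiducial")))
    sum(render_scan(cfg)$scan$voxels)
  }, numeric(1))
  cv <- fit_standard_curve(sums, c(0.55, 1.1, 2.2), mode = "origin")
  expect_equal(cv$slope, 1 / 1000, tolerance = 1e-6)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
})

test_that("ratio-method arithmetic is the pixel-sum ratio times known iron", {
  expect_equal(estimate_tiv_ratio(100, 100, 2.2)$total_tiv_ug, 2.2)
  expect_equal(estimate_tiv_ratio(0, 500, 2.2)$total_tiv_ug, 0)
  expect_equal(estimate_tiv_ratio(250, 500, 2.2)$total_tiv_ug, 1.1)
  expect_error(estimate_tiv_ratio(10, 0, 2.2), "> 0")
})

test_that("zero graft signal quantifies to zero TIV", {
  s <- make_phantom_series(0, config = quiet_config(grid = c(36L, 64L, 64L)))[[1]]
  q <- quantify_scan(s$scan, standard_fiducials(), seed = 42)
  expect_equal(q$tiv$total_tiv_ug, 0)
})

test_that("total TIV is the sum of per-slice TIVs and is partition-invariant", {
  out <- graft_scan(2)
  q <- quantify_scan(out$scan, out$fiducials, seed = 42)
  expect_equal(q$tiv$total_tiv_ug, sum(q$tiv$per_slice_tiv_ug))
  # merging adjacent slice sums (a coarser partition of the same graft)
  # leaves the origin-mode total unchanged
  seg <- q$segmentation
  merged <- tapply(seg$graft_slice_sums,
                   rep(1:18, each = 2), sum)
  seg$graft_slice_sums <- as.numeric(merged)
  q2 <- estimate_tiv_curve(seg, q$curve)
  expect_equal(q2$total_tiv_ug, q$tiv$total_tiv_ug, tolerance = 1e-12)
})

test_that("curve and ratio methods agree for a single-point origin curve", {
  out <- graft_scan(1.3)
  q <- quantify_scan(out$scan, out$fiducials, seed = 42)
  fid40 <- q$fiducial_table[q$fiducial_table$fiducial_id == "fid40", ]
  cv1 <- fit_standard_curve(fid40$pixel_sum, fid40$iron_ug, mode = "origin")
  qc <- estimate_tiv_curve(q$segmentation, cv1)
  qr <- estimate_tiv_ratio(sum(q$segmentation$graft_slice_sums),
                           fid40$pixel_sum, fid40$iron_ug)
  expect_equal(qc$total_tiv_ug, qr$total_tiv_ug, tolerance = 1e-12)
})

test_that("estimation without resolved graft components errors", {
  out <- graft_scan(1)
  seg <- segment_volume(out$scan, k = 4, policy = "topm:3", seed = 42)
  cv <- fit_standard_curve(c(100), c(0.55), mode = "origin")
  expect_error(estimate_tiv_curve(seg, cv), "separate_fiducials")
  expect_error(estimate_tiv_curve(NULL, cv), "separate_fiducials")
  expect_error(estimate_tiv_curve(seg, NULL), "calibration")
})

test_that("longitudinal summary orders days and aggregates correctly", {
  est <- list("28" = c(2.1, 1.9), "1" = 4.0, "7" = c(5.2, 4.8, 5.0))
  tab <- longitudinal_summary(est)
  expect_equal(tab$day, c(1, 7, 28))
  expect_equal(tab$n, c(1L, 3L, 2L))
  expect_equal(tab$mean_tiv_ug, c(4, 5, 2))
  expect_equal(tab$sd_tiv_ug[1], 0)
  # permuting the input order does not change the output
  tab2 <- longitudinal_summary(est[c(2, 3, 1)])
  expect_equal(tab, tab2, ignore_attr = TRUE)
  expect_error(longitudinal_summary(list("1" = numeric(0))), "no estimates")
})
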
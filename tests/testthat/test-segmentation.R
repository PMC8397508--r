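# Layer-by-layer segmentation, components and fiducial separation.

test_that("a separable bright blob is masked exactly", {
  sl <- matrix(0, 16, 16)
  sl[5:7, 9:11] <- 1000 + seq_len(9)
  seg <- segment_slice(sl, k = 2, seed = 1)
  expect_identical(seg$mask, sl > 0)
  expect_equal(seg$roi_pixel_sum, sum(sl))
})

test_that("an all-zero slice yields an empty mask", {
  seg <- segment_slice(matrix(0, 10, 10), k = 4)
  expect_false(any(seg$mask))
  expect_equal(seg$roi_pixel_sum, 0)
  expect_true(seg$flagged)
})

test_that("four intensity tiers are cut at the top-two-centroid midpoint", {
  fx <- tier_slice(levels = c(5, 50, 500))
  seg <- segment_slice(fx$slice, k = 4, seed = 2)
  expect_identical(seg$mask, fx$masks$tier3)
  cents <- seg$model$centroids
  thr <- mean(cents[3:4])
  expect_identical(seg$mask, fx$slice > thr)
  expect_equal(seg$roi_pixel_sum, sum(fx$slice[fx$slice > thr]))
})

test_that("topm policy keeps the m brightest clusters but never background", {
  fx <- tier_slice(levels = c(5, 50, 500))
  seg <- segment_slice(fx$slice, k = 4, policy = "topm:2", seed = 2)
  expect_identical(seg$mask, fx$masks$tier2 | fx$masks$tier3)
  # m larger than k-1 is capped: background stays out
  seg_all <- segment_slice(fx$slice, k = 4, policy = "topm:9", seed = 2)
  expect_identical(seg_all$mask, !fx$masks$background)
})

test_that("a slice with fewer distinct values than k falls back and flags", {
  sl <- matrix(c(0, 0, 0, 7), 2, 2)
  seg <- segment_slice(sl, k = 4, seed = 1)
  expect_true(seg$flagged)
  expect_equal(seg$k_used, 2L)
  expect_identical(seg$mask, sl == 7)
})

test_that("segment_volume returns one segmentation per slice", {
  out <- graft_scan(2)
  seg <- segment_volume(out$scan, k = 4, policy = "topm:3", seed = 42)
  expect_length(seg$slices, 36)
  expect_equal(vapply(seg$slices, `[[`, integer(1), "slice_index"), 1:36)
  expect_identical(dim(seg$mask), dim(out$scan$voxels))
})

test_that("a volume of zeros segments to all-empty masks", {
  seg <- segment_volume(array(0, c(5, 8, 8)), k = 4, seed = 1)
  expect_false(any(seg$mask))
})

test_that("stacking identical slices gives identical per-slice masks", {
  fx <- tier_slice(levels = c(5, 50, 500))
  vol <- aperm(array(fx$slice, c(dim(fx$slice), 4)), c(3, 1, 2))
  seg <- segment_volume(vol, k = 4, policy = "top1", seed = 9,
                        grow_mask = FALSE, noise_floor = 0)
  for (z in 2:4)
    expect_identical(seg$slices[[z]]$mask, seg$slices[[1]]$mask)
})

test_that("masks are invariant under positive affine intensity rescaling", {
  out <- graft_scan(2)
  seg1 <- segment_volume(out$scan, k = 4, policy = "topm:3", seed = 7)
  rescaled <- scan_volume(out$scan$voxels * 3.7 + 11,
                          voxel_size = out$scan$voxel_size)
  seg2 <- segment_volume(rescaled, k = 4, policy = "topm:3", seed = 7)
  expect_identical(seg1$mask, seg2$mask)
})

test_that("noise-free separable fixtures recover blob voxels exactly", {
  vol <- array(0, c(6, 12, 12))
  vol[2:4, 3:5, 3:5] <- 800
  vol[5, 9:10, 9:10] <- 820
  seg <- segment_volume(vol, k = 2, policy = "top1", seed = 1)
  expect_identical(seg$mask, vol > 0)
})

test_that("per-slice ROI sums add up to the 3D mask pixel sum", {
  out <- graft_scan(2, noisy = TRUE)
  seg <- segment_volume(out$scan, k = 4, policy = "topm:3", seed = 42)
  expect_equal(sum(vapply(seg$slices, `[[`, numeric(1), "roi_pixel_sum")),
               sum(out$scan$voxels[seg$mask]))
})

test_that("connected components split and count blobs correctly", {
  m <- array(FALSE, c(4, 8, 8))
  m[1:2, 1:2, 1:2] <- TRUE
  m[4, 6:7, 6:7] <- TRUE
  v <- array(1, dim(m))
  cs <- label_components(m, v)
  expect_length(cs$components, 2)
  expect_equal(sort(vapply(cs$components, `[[`, numeric(1), "pixel_sum")),
               c(4, 8))
  expect_length(label_components(array(FALSE, c(3, 3, 3)))$components, 0)
  # components are disjoint and cover the mask
  expect_equal(sum(vapply(cs$components, `[[`, numeric(1), "size")), sum(m))
  expect_identical(cs$labels > 0, m)
})

test_that("diagonal voxels connect at 26- but not 6-connectivity", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_length(label_components(m, connectivity = 26)$components, 1)
  expect_length(label_components(m, connectivity = 6)$components, 2)
})

test_that("fiducials match their components and the graft remains", {
  out <- graft_scan(2)
  seg <- segment_volume(out$scan, k = 4, policy = "topm:3", seed = 42)
  seg <- separate_fiducials(seg, out$scan, out$fiducials)
  expect_equal(nrow(seg$fiducial_map), 3)
  expect_length(seg$graft_components, 1)
  gc <- mpiquant:::default_graft_center(c(36L, 64L, 64L))
  expect_equal(seg$graft_components[[1]]$centroid, gc, tolerance = 0.1)
})

test_that("each fiducial takes its nearest component, not an interloper", {
  # two blobs: the true fiducial at the expected center and a brighter
  # graft inside the search radius but farther away
  vol <- array(0, c(5, 20, 20))
  vol[3, 10, 5] <- 500
  vol[3, 10, 9] <- 900
  comps <- label_components(vol > 0, vol)
  fid <- fiducial_spec("f", c(3, 10, 5), 0.4, search_radius = 6)
  asn <- assign_fiducials(comps, list(fid))
  expect_equal(asn$fiducial_components[[1]]$pixel_sum, 500)
  expect_equal(asn$graft_components[[1]]$pixel_sum, 900)
})

test_that("a missing fiducial is a calibration error", {
  vol <- array(0, c(5, 20, 20))
  vol[3, 10, 5] <- 500
  comps <- label_components(vol > 0, vol)
  fids <- list(fiducial_spec("present", c(3, 10, 5), 0.4),
               fiducial_spec("absent", c(3, 3, 15), 0.2))
  expect_error(assign_fiducials(comps, fids), "absent")
})
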
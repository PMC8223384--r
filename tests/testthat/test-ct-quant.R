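test_that("median filter removes an isolated hot voxel and keeps uniforms", {
  arr <- array(40, dim = c(16, 16, 1))
  arr[8, 8, 1] <- 1000
  vol <- image_volume(arr, c(1.2, 1.2, 3), "HU")
  out <- median_filter_ct(vol, 3)
  expect_equal(out$data[8, 8, 1], 40)

  unif <- image_volume(array(75, dim = c(10, 10, 2)), c(1.2, 1.2, 3), "HU")
  expect_equal(median_filter_ct(unif, 3)$data, unif$data)
})

test_that("median filter preserves the interior of a large square", {
  arr <- array(40, dim = c(20, 20, 1))
  arr[7:14, 7:14, 1] <- 400   # 8x8 square
  vol <- image_volume(arr, c(1.2, 1.2, 3), "HU")
  out <- median_filter_ct(vol, 3)
  expect_true(all(out$data[9:12, 9:12, 1] == 400))
  # and matches the brute-force circular-kernel oracle everywhere
  expect_equal(out$data[, , 1],
               oracle_median_slice(arr[, , 1], 3, 1.2, 1.2))
})

test_that("median filter matches the brute-force oracle on a random slice", {
  withr::with_seed(77, arr <- array(rnorm(12 * 12), dim = c(12, 12, 1)))
  vol <- image_volume(arr, c(1.2, 1.2, 3), "HU")
  expect_equal(median_filter_ct(vol, 2.5)$data[, , 1],
               oracle_median_slice(arr[, , 1], 2.5, 1.2, 1.2))
})

test_that("radius 0 disables filtering; anisotropic spacing needs opt-in", {
  vol <- image_volume(array(rnorm(64), dim = c(4, 4, 4)), c(1.2, 1.2, 3), "HU")
  expect_identical(median_filter_ct(vol, 0), vol)
  aniso <- image_volume(array(0, dim = c(4, 4, 4)), c(1, 2, 3), "HU")
  expect_error(median_filter_ct(aniso, 3), "anisotropic")
  expect_s3_class(median_filter_ct(aniso, 3, allow_anisotropic = TRUE),
                  "image_volume")
})

test_that("filter is idempotent on piecewise-constant regions larger than the kernel", {
  # a straight step edge is a root signal of the disc-kernel median: the
  # filter leaves it unchanged, hence is idempotent on it
  arr <- array(40, dim = c(24, 24, 1))
  arr[9:16, , 1] <- 400   # full-width band, straight edges only
  vol <- image_volume(arr, c(1.2, 1.2, 3), "HU")
  once <- median_filter_ct(vol, 3)
  expect_equal(once$data, arr)
  expect_equal(median_filter_ct(once, 3)$data, once$data)
})

test_that("the 130 HU threshold is inclusive", {
  f <- one_slice_volume(c(129.99, 130.0, 40, 40), background = -50)
  f$volume$units <- "HU"
  res <- segment_calcium_ct(f$volume, f$roi, f$segment,
                            ct_config(median_radius_mm = 0))
  expect_identical(sum(res$mask), 1L)
  expect_true(res$mask[2, 1, 1])
})

test_that("a uniform blood pool yields zero volume; 9 voxels give 38.88 mm3", {
  blood <- one_slice_volume(rep(40, 20), background = -50)
  blood$volume$units <- "HU"
  res0 <- segment_calcium_ct(blood$volume, blood$roi, blood$segment,
                             ct_config(median_radius_mm = 0))
  expect_identical(res0$total_volume_mm3, 0)

  nine <- one_slice_volume(c(rep(500, 9), rep(40, 11)), background = -50)
  nine$volume$units <- "HU"
  res9 <- segment_calcium_ct(nine$volume, nine$roi, nine$segment,
                             ct_config(median_radius_mm = 0))
  expect_equal(res9$per_slice$area_mm2, 9 * 1.44)
  expect_equal(res9$per_slice$area_mm2, 12.96)
  expect_equal(res9$total_volume_mm3, 38.88)
})

test_that("CT segmentation enforces units, ROI coverage and mask containment", {
  p <- demo_phantom()
  seg <- demo_segment(p)
  expect_error(segment_calcium_ct(p$mr, p$roi, seg), "Hounsfield")
  empty_roi <- roi_mask(array(FALSE, dim(p$roi$data)), p$roi$spacing)
  expect_error(segment_calcium_ct(p$ct, empty_roi, seg), "empty")
  res <- segment_calcium_ct(p$ct, p$roi, seg, ct_config(median_radius_mm = 0))
  expect_true(all(p$roi$data[res$mask]))                 # mask inside ROI
  flagged_slices <- which(apply(res$mask, 3, any)) - 1L
  expect_true(all(flagged_slices %in% seg$slices))       # mask inside segment
})

test_that("detected volume is monotone non-increasing in the HU threshold", {
  p <- make_paired_phantom(phantom_spec(lesions = demo_lesions(),
                                        ct_noise_sd = 30, seed = 4L))
  seg <- demo_segment(p)
  vols <- vapply(c(100, 130, 200, 400, 800), function(thr) {
    segment_calcium_ct(p$ct, p$roi, seg,
                       ct_config(threshold_hu = thr,
                                 median_radius_mm = 0))$total_volume_mm3
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("volume formula handles direct, empty and single-term cases", {
  expect_equal(compute_volume(c(10, 20, 0), 3), 90)
  expect_identical(compute_volume(numeric(0), 3), 0)
  expect_equal(compute_volume(1.44, 3), 4.32)
  expect_error(compute_volume(c(1, -2), 3), ">= 0")
  expect_error(compute_volume(10, 0), "positive")
})

test_that("Agatston scoring applies density bins and the area floor", {
  # one lesion of 4 voxels at 0.25 mm2 each, max 250 HU -> 1.0 mm2 x 2
  arr <- array(0, dim = c(6, 6, 1))
  arr[3, 3:4, 1] <- c(250, 140); arr[4, 3:4, 1] <- c(135, 132)
  vol <- image_volume(arr, c(0.5, 0.5, 3), "HU")
  roi <- roi_mask(array(TRUE, dim(arr)), c(0.5, 0.5, 3))
  res <- agatston_score(vol, roi, ct_config(median_radius_mm = 0))
  expect_identical(nrow(res$lesions), 1L)
  expect_equal(res$lesions$area_mm2, 1.0)
  expect_identical(res$lesions$weight, 2L)
  expect_equal(res$total, 2.0)

  # below the 1 mm2 floor: 2 voxels = 0.5 mm2 -> excluded
  arr2 <- array(0, dim = c(6, 6, 1)); arr2[3, 3:4, 1] <- 300
  res2 <- agatston_score(image_volume(arr2, c(0.5, 0.5, 3), "HU"), roi)
  expect_identical(res2$total, 0)

  # nothing above threshold
  arr3 <- array(40, dim = c(6, 6, 1))
  expect_identical(
    agatston_score(image_volume(arr3, c(0.5, 0.5, 3), "HU"), roi)$total, 0)
})

test_that("Agatston weights are monotone in max HU across the bins", {
  roi <- roi_mask(array(TRUE, c(4, 4, 1)), c(1, 1, 3))
  score_at <- function(hu) {
    arr <- array(0, dim = c(4, 4, 1)); arr[2, 2:3, 1] <- hu
    agatston_score(image_volume(arr, c(1, 1, 3), "HU"), roi)$lesions$weight
  }
  expect_identical(vapply(c(130, 199, 200, 299, 300, 399, 400, 1000),
                          score_at, integer(1)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
})

test_that("Agatston total is invariant to slice order and connectivity splits lesions", {
  p <- make_paired_phantom(phantom_spec(lesions = demo_lesions(), seed = 2L))
  seg <- demo_segment(p)
  full <- agatston_score(p$ct, p$roi, ct_config(), seg)
  # score each slice separately and sum
  per_slice <- vapply(sample(seg$slices), function(s) {
    seg1 <- list(slices = s, n_slices = 1L)
    class(seg1) <- "segment_selection"
    agatston_score(p$ct, p$roi, ct_config(), seg1)$total
  }, numeric(1))
  expect_equal(sum(per_slice), full$total)

  # two diagonal voxels: separate under 4-connectivity, joined under 8
  arr <- array(0, dim = c(6, 6, 1))
  arr[2, 2, 1] <- 200; arr[3, 3, 1] <- 450
  vol <- image_volume(arr, c(1.5, 1.5, 3), "HU")
  roi <- roi_mask(array(TRUE, dim(arr)), c(1.5, 1.5, 3))
  r4 <- agatston_score(vol, roi, ct_config(connectivity = 4))
  r8 <- agatston_score(vol, roi, ct_config(connectivity = 8))
  expect_identical(nrow(r4$lesions), 2L)
  expect_identical(nrow(r8$lesions), 1L)
  expect_identical(r8$lesions$weight, 4L)
})
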
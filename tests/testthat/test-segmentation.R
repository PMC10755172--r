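test_that("a constant image yields a degenerate, flagged threshold", {
  gray <- matrix(0.5, 60, 50)
  thr <- compute_trend_threshold(gray, seed = 0)
  expect_true(thr$degenerate)
  expect_equal(mean(thr$surface), 0.5, tolerance = 1e-6)
  mask <- binarize_and_clean(gray, thr$surface, final_clean = 0)
  expect_true(all(mask == 0) || all(mask == 1))
})

test_that("the trend threshold is deterministic given its seed", {
  spec <- kernel_scan_spec(n_kernels = 4, canvas = c(260, 220))
  gray <- luminance(generate_kernel_scan(spec, seed = 3)$image)
  a <- compute_trend_threshold(gray, seed = 0)
  b <- compute_trend_threshold(gray, seed = 0)
  expect_identical(a$surface, b$surface)
})

test_that("kernels are recovered under an illumination gradient", {
  spec <- kernel_scan_spec(n_kernels = 2, canvas = c(320, 240),
                           background_gradient = 45)
  scan <- generate_kernel_scan(spec, seed = 8)
  seg <- segment_scan(scan$image)
  expect_equal(seg$labeled$n_components, 2)
  # each truth kernel overlaps a recovered component by > 80%
  for (k in 1:2) {
    tm <- scan$truth$labels == k
    expect_gt(sum(tm & seg$labeled$labels > 0) / sum(tm), 0.8)
  }
})

test_that("speckles are cleaned away and holes are filled", {
  # pure speckle noise (<= 2 px blobs) leaves an empty foreground
  gray <- matrix(0.06, 150, 150)
  set.seed(1)
  idx <- cbind(sample(5:145, 20), sample(5:145, 20))
  gray[idx] <- 0.9
  gray[idx + 1] <- 0.9
  mask <- binarize_and_clean(gray, 0.5)
  expect_equal(sum(mask), 0)

  # a 5 px interior hole in a solid kernel is filled (closing may smooth
  # the discrete boundary outward slightly, so compare by containment)
  solid <- ellipse_mask(30, 18)
  holed <- solid
  holed[28:32, 16:18] <- 0L
  gray2 <- 0.06 + 0.8 * holed
  cleaned <- binarize_and_clean(gray2, 0.5, final_clean = 0)
  expect_true(all(cleaned[solid == 1L] == 1L))
  expect_lt(sum(cleaned) / sum(solid), 1.2)
})

test_that("debris blobs do not survive as components", {
  spec <- kernel_scan_spec(n_kernels = 10, canvas = c(520, 420),
                           debris_count = 3)
  scan <- generate_kernel_scan(spec, seed = 6)
  seg <- segment_scan(scan$image)
  expect_equal(seg$labeled$n_components, 10)
})

test_that("watershed separates touching kernels", {
  spec <- kernel_scan_spec(n_kernels = 2, canvas = c(300, 260),
                           touching_pairs = 1)
  scan <- generate_kernel_scan(spec, seed = 14)
  seg <- segment_scan(scan$image)
  expect_equal(seg$labeled$n_components, 2)
})

test_that("component labeling has set semantics", {
  m <- matrix(0L, 60, 60)
  m[5:20, 5:20] <- 1L
  m[35:55, 35:55] <- 1L
  lab <- split_components(m, use_watershed = FALSE)
  expect_equal(lab$n_components, 2)
  # union of components equals the foreground; components disjoint
  expect_identical(lab$labels > 0, m > 0)
  empty <- split_components(matrix(0L, 30, 30))
  expect_equal(empty$n_components, 0)
})

test_that("the component count is invariant to small speckle noise", {
  spec <- kernel_scan_spec(n_kernels = 8, canvas = c(420, 340))
  scan <- generate_kernel_scan(spec, seed = 17)
  base_count <- segment_scan(scan$image)$labeled$n_components
  noisy <- scan$image
  set.seed(3)
  for (i in 1:15) {
    x <- sample(10:410, 1); y <- sample(10:330, 1)
    noisy[x:(x + 1), y:(y + 1), ] <- 250
  }
  expect_equal(segment_scan(noisy)$labeled$n_components, base_count)
})
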
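test_that("contour length tracks the perimeter and small blobs are flagged", {
  rect <- matrix(0L, 220, 120)
  rect[11:210, 11:110] <- 1L   # 200 x 100 rectangle
  ctr <- trace_contour(rect)
  expect_true(ctr$retained)
  expect_lt(abs(ctr$n_points - 600), 60)

  blob <- matrix(0L, 12, 12); blob[4:8, 4:8] <- 1L
  expect_false(trace_contour(blob)$retained)

  expect_error(trace_contour(matrix(0L, 10, 10)), "zero area")
})

test_that("circle contours are equidistant from the center", {
  m <- ellipse_mask(40, 40)
  ctr <- trace_contour(m)
  center <- colMeans(ctr$xy)
  d <- sqrt(rowSums(sweep(ctr$xy, 2, center)^2))
  expect_lt(max(d) - min(d), 2)  # 1 px discretization on either side
})

test_that("tip/base come from the maximal pairwise distance (exhaustive oracle)", {
  # analytic ellipse: major axis endpoints, length ~ 160
  e <- ellipse_mask(80, 40)
  ctr <- trace_contour(e)
  tb <- locate_tip_base(ctr$xy)
  expect_lt(abs(tb$length - 160), 3)
  expect_lt(abs(tb$end1[2] - tb$end2[2]), 8)  # both near the major axis

  # brute-force all-pairs maximum on an irregular kernel contour
  spec <- kernel_scan_spec(n_kernels = 1, canvas = c(200, 170))
  scan <- generate_kernel_scan(spec, seed = 9)
  km <- (scan$truth$labels == 1) * 1L
  kc <- trace_contour(km)
  tb2 <- locate_tip_base(kc$xy)
  brute <- max(stats::dist(kc$xy))
  expect_equal(tb2$length, brute, tolerance = 1e-12)
})

test_that("circle diameter ties break deterministically", {
  m <- ellipse_mask(30, 30)
  ctr <- trace_contour(m)
  a <- locate_tip_base(ctr$xy)
  b <- locate_tip_base(ctr$xy)
  expect_identical(a$idx, b$idx)
  expect_lt(abs(a$length - 60), 2)
})

test_that("width is the perpendicular chord through the center", {
  circ <- trace_contour(ellipse_mask(35, 35))
  center <- colMeans(circ$xy)
  tipc <- locate_tip_base(circ$xy)
  wc <- measure_width(circ$xy, center, tipc$end1)
  expect_true(wc$obtainable)
  expect_lt(abs(wc$width - 70), 3)

  ell <- trace_contour(ellipse_mask(80, 40))
  tbe <- locate_tip_base(ell$xy)
  we <- measure_width(ell$xy, colMeans(ell$xy), tbe$end1)
  expect_lt(abs(we$width - 80), 4)

  # a 1-px line has no contour point near 90 degrees
  line <- matrix(0L, 60, 9); line[10:50, 5] <- 1L
  lc <- trace_contour(line)
  tbl <- locate_tip_base(lc$xy)
  wl <- measure_width(lc$xy, colMeans(lc$xy), tbl$end1)
  expect_false(wl$obtainable)
})

test_that("the axial region is the prescribed band of the tip-base span", {
  rect <- matrix(0L, 120, 60)
  rect[11:110, 21:40] <- 1L   # 100 px long, axis-aligned
  tip <- c(11, 30); base <- c(110, 30)
  reg <- axial_region_mask(rect, tip, base)
  expect_lt(abs(reg$n_pixels / sum(rect) - 0.55), 0.03)
  pix <- which(reg$region > 0, arr.ind = TRUE)
  tt <- (pix[, 1] - 11) / 99
  expect_gt(min(tt), 0.30 - 0.02)
  expect_lt(max(tt), 0.85 + 0.02)
  # region is a subset of the mask
  expect_true(all(rect[reg$region > 0] == 1))

  full <- axial_region_mask(rect, tip, base, cut_tip = 0, cut_base = 0)
  expect_equal(sum(full$region), sum(rect))
})

test_that("the cap band is excluded from the color-sampling region", {
  spec <- kernel_scan_spec(n_kernels = 1, canvas = c(220, 180), cap_frac = 0.12)
  scan <- generate_kernel_scan(spec, seed = 13)
  km <- (scan$truth$labels == 1) * 1L
  ctr <- trace_contour(km)
  tb <- locate_tip_base(ctr$xy)
  ori <- orient_tip_base(km, tb$end1, tb$end2, image = scan$image)
  reg <- axial_region_mask(km, ori$tip, ori$base)
  cap <- scan$truth$cap_labels == 1
  expect_equal(sum(reg$region > 0 & cap), 0)
  expect_equal(ori$rule, "color")
})

test_that("length, width and region area are rotation invariant", {
  spec <- kernel_scan_spec(n_kernels = 1, canvas = c(220, 180))
  scan <- generate_kernel_scan(spec, seed = 23)
  km <- (scan$truth$labels == 1) * 1L
  rot <- t(km)[ncol(km):1, ]  # 90 degree rotation

  stats_of <- function(m) {
    ctr <- trace_contour(m)
    tb <- locate_tip_base(ctr$xy)
    w <- measure_width(ctr$xy, colMeans(ctr$xy), tb$end1)
    reg <- axial_region_mask(m, tb$end1, tb$end2)
    c(tb$length, w$width, reg$n_pixels)
  }
  a <- stats_of(km); b <- stats_of(rot)
  expect_equal(a, b, tolerance = 0.02)
})
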
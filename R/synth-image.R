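#' Parameters for a synthetic kernel-scan image
#'
#' Describes a flatbed-scan-like image: ovoid maize kernels spread on a
#' near-black background, each with a body color drawn around a target hue,
#' a lighter yellow "cap" band at the base end (endosperm showing through)
#' and a slightly darker tip zone. Optional features exercise the
#' segmentation and QC stages: touching kernel pairs, small debris blobs,
#' damaged (notched) kernels, an illumination gradient and pixel noise.
#'
#' All geometry is in pixels; colors are 8-bit RGB. Hue/saturation/value
#' defaults put kernel luminance well above the 0.4 minimum-luminance
#' threshold of the segmentation stage, as on a real scanner.
#'
#' @param n_kernels Number of kernels.
#' @param canvas `c(width, height)` of the image in pixels.
#' @param length_px,width_px Ranges (min, max) for kernel length and width.
#' @param body_hue Target body hue in degrees (per-kernel hues are drawn
#'   `body_hue + N(0, hue_sd)`).
#' @param hue_sd Per-kernel hue SD in degrees.
#' @param body_s,body_v HSV saturation and value of the kernel body.
#' @param cap_frac,tip_frac Axial fractions of the kernel occupied by the
#'   basal cap band and the tip zone.
#' @param touching_pairs Number of kernel pairs placed side-by-side so their
#'   masks touch.
#' @param debris_count Number of small (radius <= 4 px) debris blobs.
#' @param damaged_frac Fraction of kernels given a notch (chipped kernel).
#' @param background Background RGB (near black).
#' @param background_gradient Peak-to-peak left-to-right luminance gradient
#'   added to the background, in 8-bit counts.
#' @param noise_sd SD of additive Gaussian pixel noise (8-bit counts).
#' @return A list of class `kernel_scan_spec`.
#' @export
kernel_scan_spec <- function(n_kernels = 60, canvas = c(900, 700),
                             length_px = c(42, 58), width_px = c(26, 34),
                             body_hue = 33, hue_sd = 2,
                             body_s = 0.75, body_v = 0.8,
                             cap_frac = 0.12, tip_frac = 0.08,
                             touching_pairs = 0, debris_count = 0,
                             damaged_frac = 0,
                             background = c(15, 15, 15),
                             background_gradient = 0, noise_sd = 2) {
  stopifnot(n_kernels >= 0, length(canvas) == 2, all(canvas > 0),
            length_px[1] <= length_px[2], width_px[1] <= width_px[2],
            width_px[1] > 0, all(background >= 0 & background <= 255))
  structure(as.list(environment()), class = "kernel_scan_spec")
}

# half-width profile of an ovoid kernel: u in [0,1] runs base -> tip;
# the exponent grows toward the tip so the tip tapers to a point while the
# base stays blunt
.kernel_halfwidth <- function(u, width) {
  p <- 0.32 + 0.45 * u
  (width / 2) * pmax(0, 4 * u * (1 - u))^p
}

.hsv_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h / 360, s, v)))
}

#' Generate a synthetic kernel-scan image with ground truth
#'
#' Renders the scene described by a [kernel_scan_spec()] and records every
#' kernel's placement, colors and pixel mask, so segmentation and color
#' phenotyping can be validated against known truth.
#'
#' @param spec A [kernel_scan_spec()].
#' @param seed Integer seed; the image is bit-reproducible given it.
#' @return List with `image` (width x height x 3 array, 0-255) and `truth`:
#'   `kernel_count`, `per_kernel` (data frame: id, center, angle, length,
#'   width, body/cap/tip RGB, body hue, damaged), `labels` (width x height
#'   matrix, 0 = background, k = kernel k), `cap_labels` (same but only cap
#'   pixels), `debris_count`, `background`.
#' @export
generate_kernel_scan <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "kernel_scan_spec"))
  set.seed(seed)
  W <- spec$canvas[1]; H <- spec$canvas[2]

  img <- array(0, dim = c(W, H, 3))
  xg <- matrix(seq_len(W), W, H)
  grad <- if (spec$background_gradient > 0) {
    spec$background_gradient * (xg - 1) / max(W - 1, 1)
  } else 0
  for (c3 in 1:3) img[, , c3] <- spec$background[c3] + grad

  labels <- matrix(0L, W, H)
  cap_labels <- matrix(0L, W, H)

  n <- spec$n_kernels
  per_kernel <- NULL
  if (n > 0) {
    len <- stats::runif(n, spec$length_px[1], spec$length_px[2])
    wid <- stats::runif(n, spec$width_px[1], spec$width_px[2])
    hue <- spec$body_hue + stats::rnorm(n, 0, spec$hue_sd)
    damaged <- stats::runif(n) < spec$damaged_frac
    angle <- stats::runif(n, 0, 2 * pi)

    # touching pairs share an orientation and sit side by side
    pair_of <- rep(NA_integer_, n)
    if (spec$touching_pairs > 0) {
      np <- min(spec$touching_pairs, floor(n / 2))
      for (p in seq_len(np)) {
        i <- 2 * p - 1; j <- 2 * p
        pair_of[j] <- i
        angle[j] <- angle[i]
      }
    }

    margin <- max(len) / 2 + 4
    if (2 * margin >= min(W, H)) stop("canvas too small for requested kernels")
    cx <- numeric(n); cy <- numeric(n)
    placed_r <- len / 2 + 3
    for (i in seq_len(n)) {
      if (!is.na(pair_of[i])) {
        j <- pair_of[i]
        # offset perpendicular to the shared axis so the flanks touch
        d <- (wid[i] + wid[j]) / 2 * 0.96
        cx[i] <- cx[j] - d * sin(angle[i])
        cy[i] <- cy[j] + d * cos(angle[i])
        next
      }
      ok <- FALSE
      for (try in seq_len(500)) {
        x0 <- stats::runif(1, margin, W - margin)
        y0 <- stats::runif(1, margin, H - margin)
        prev <- seq_len(i - 1)
        prev <- prev[is.na(pair_of[prev]) | pair_of[prev] < i]
        # pair leaders need extra clearance for their touching partner
        extra <- if (i %in% pair_of) wid[i] + 2 else 0
        if (i == 1 || all(sqrt((cx[prev] - x0)^2 + (cy[prev] - y0)^2) >
                          placed_r[prev] + placed_r[i] + 2 + extra)) {
          cx[i] <- x0; cy[i] <- y0; ok <- TRUE; break
        }
      }
      if (!ok) stop("impossible placement: too many kernels for canvas")
    }

    body_rgb <- t(vapply(hue, .hsv_rgb, numeric(3),
                         s = spec$body_s, v = spec$body_v))
    cap_rgb <- t(vapply(hue, function(h) .hsv_rgb(52, 0.55, min(1, spec$body_v * 1.15)),
                        numeric(3)))
    tip_rgb <- t(vapply(hue, function(h) .hsv_rgb(max(h - 4, 0), min(1, spec$body_s * 1.1),
                                                  spec$body_v * 0.88),
                        numeric(3)))

    for (i in seq_len(n)) {
      bb_x <- max(1, floor(cx[i] - len[i])):min(W, ceiling(cx[i] + len[i]))
      bb_y <- max(1, floor(cy[i] - len[i])):min(H, ceiling(cy[i] + len[i]))
      px <- rep(bb_x, times = length(bb_y))
      py <- rep(bb_y, each = length(bb_x))
      dx <- px - cx[i]; dy <- py - cy[i]
      a <- dx * cos(angle[i]) + dy * sin(angle[i])   # axial, base at -L/2
      p <- -dx * sin(angle[i]) + dy * cos(angle[i])  # perpendicular
      u <- (a + len[i] / 2) / len[i]
      inside <- u >= 0 & u <= 1 & abs(p) <= .kernel_halfwidth(u, wid[i])
      if (damaged[i]) {
        # notch: bite a chunk out of one flank near mid-kernel
        nu <- stats::runif(1, 0.35, 0.65)
        npx <- cx[i] + (nu - 0.5) * len[i] * cos(angle[i]) -
          .kernel_halfwidth(nu, wid[i]) * sin(angle[i])
        npy <- cy[i] + (nu - 0.5) * len[i] * sin(angle[i]) +
          .kernel_halfwidth(nu, wid[i]) * cos(angle[i])
        nr <- stats::runif(1, 0.45, 0.7) * wid[i] / 2 + 2
        inside <- inside & ((px - npx)^2 + (py - npy)^2 > nr^2)
      }
      sel <- cbind(px[inside], py[inside])
      if (nrow(sel) == 0) next
      usel <- u[inside]
      zone_cap <- usel < spec$cap_frac
      zone_tip <- usel > 1 - spec$tip_frac
      col <- matrix(body_rgb[i, ], nrow(sel), 3, byrow = TRUE)
      if (any(zone_cap)) col[zone_cap, ] <- matrix(cap_rgb[i, ], sum(zone_cap), 3, byrow = TRUE)
      if (any(zone_tip)) col[zone_tip, ] <- matrix(tip_rgb[i, ], sum(zone_tip), 3, byrow = TRUE)
      for (c3 in 1:3) img[, , c3][sel] <- col[, c3]
      labels[sel] <- i
      if (any(zone_cap)) cap_labels[sel[zone_cap, , drop = FALSE]] <- i
    }

    # ground-truth hue is that of the 8-bit body color actually rendered
    # (quantization shifts it slightly from the requested target)
    achieved_hue <- kernel_hue(body_rgb[, 1], body_rgb[, 2], body_rgb[, 3])$hue
    per_kernel <- data.frame(
      id = seq_len(n), cx = cx, cy = cy, angle_deg = angle * 180 / pi,
      length_px = len, width_px = wid, hue = achieved_hue, hue_target = hue,
      body_r = body_rgb[, 1], body_g = body_rgb[, 2], body_b = body_rgb[, 3],
      cap_r = cap_rgb[, 1], cap_g = cap_rgb[, 2], cap_b = cap_rgb[, 3],
      tip_r = tip_rgb[, 1], tip_g = tip_rgb[, 2], tip_b = tip_rgb[, 3],
      damaged = damaged)
  }

  # debris: small dull blobs kept clear of the kernels
  if (spec$debris_count > 0) {
    for (d in seq_len(spec$debris_count)) {
      for (try in seq_len(200)) {
        x0 <- stats::runif(1, 10, W - 10); y0 <- stats::runif(1, 10, H - 10)
        r <- stats::runif(1, 2, 4)
        if (n == 0 || all(sqrt((per_kernel$cx - x0)^2 + (per_kernel$cy - y0)^2) >
                          per_kernel$length_px / 2 + r + 12)) break
      }
      px <- max(1, floor(x0 - r)):min(W, ceiling(x0 + r))
      py <- max(1, floor(y0 - r)):min(H, ceiling(y0 + r))
      gx <- rep(px, times = length(py)); gy <- rep(py, each = length(px))
      inside <- (gx - x0)^2 + (gy - y0)^2 <= r^2
      sel <- cbind(gx[inside], gy[inside])
      col <- .hsv_rgb(40, 0.4, 0.75)
      for (c3 in 1:3) img[, , c3][sel] <- col[c3]
    }
  }

  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  }
  img <- round(pmin(pmax(img, 0), 255))

  list(image = img,
       truth = list(kernel_count = spec$n_kernels, per_kernel = per_kernel,
                    labels = labels, cap_labels = cap_labels,
                    debris_count = spec$debris_count,
                    background = spec$background, seed = seed))
}
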
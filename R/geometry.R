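#' Trace the contour of a single labeled component
#'
#' Ordered boundary polygon at pixel resolution. Kernels whose contour has
#' fewer than `min_points` points are too small or too fragmented to
#' landmark reliably and are flagged for removal downstream.
#'
#' @param mask Binary width x height matrix containing one connected
#'   component (zero area is an error).
#' @param min_points Retention threshold on the contour point count
#'   (default 100).
#' @return List with `xy` (n x 2 matrix of 1-based x, y coordinates, in
#'   boundary order), `n_points` and `retained`.
#' @export
trace_contour <- function(mask, min_points = 100) {
  if (sum(mask > 0) == 0) stop("component has zero area")
  oc <- EBImage::ocontour(EBImage::Image((mask > 0) * 1))
  xy <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1  # 0-based -> 1-based
  colnames(xy) <- c("x", "y")
  list(xy = xy, n_points = nrow(xy), retained = nrow(xy) >= min_points)
}

#' Locate the tip and base of a kernel from its contour
#'
#' The tip and base are the pair of contour points at maximal Euclidean
#' distance; the kernel length is that distance. The search runs on the
#' convex hull (the diameter of a point set is attained on its hull) and is
#' checked against the exhaustive all-pairs computation in the test suite.
#' Ties are broken by the lowest contour index for determinism. Which
#' endpoint is the base is resolved separately by [orient_tip_base()].
#'
#' @param contour n x 2 matrix of contour coordinates (n >= 3).
#' @return List with `end1`, `end2` (coordinates, `end1` at the lower
#'   contour index), `idx` (their contour indices) and `length`.
#' @export
locate_tip_base <- function(contour) {
  stopifnot(nrow(contour) >= 3)
  hull <- grDevices::chull(contour)
  hp <- contour[hull, , drop = FALSE]
  d <- as.matrix(stats::dist(hp))
  best <- which(d == max(d), arr.ind = TRUE)
  # deterministic tie-break: smallest pair of original contour indices
  cand <- cbind(hull[best[, 1]], hull[best[, 2]])
  cand <- t(apply(cand, 1, sort))
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  i <- cand[1, 1]; j <- cand[1, 2]
  list(end1 = contour[i, ], end2 = contour[j, ], idx = c(i, j),
       length = sqrt(sum((contour[i, ] - contour[j, ])^2)))
}

#' Decide which kernel endpoint is the base
#'
#' The base end carries the yellow endosperm cap, so when pixel colors are
#' available the base is the endpoint whose surrounding axial band has the
#' higher yellowness (R + G - 2B). When no image is given, or the color
#' difference is negligible, a geometric fallback is used: the blunter end
#' (larger mask area in its end band) is the base, since the tip tapers.
#'
#' @param mask Binary component mask (width x height).
#' @param end1,end2 Endpoint coordinates from [locate_tip_base()].
#' @param image Optional RGB array for the color rule.
#' @param band Axial fraction of the kernel forming each end band
#'   (default 0.15).
#' @return List with `tip` and `base` coordinates and `rule` ("color" or
#'   "geometry").
#' @export
orient_tip_base <- function(mask, end1, end2, image = NULL, band = 0.15) {
  pix <- which(mask > 0, arr.ind = TRUE)
  axis <- end2 - end1
  tt <- ((pix[, 1] - end1[1]) * axis[1] + (pix[, 2] - end1[2]) * axis[2]) /
    sum(axis^2)
  b1 <- tt < band; b2 <- tt > 1 - band
  if (!is.null(image) && any(b1) && any(b2)) {
    yellow <- function(sel) {
      s <- pix[sel, , drop = FALSE]
      mean(image[, , 1][s] + image[, , 2][s] - 2 * image[, , 3][s])
    }
    y1 <- yellow(b1); y2 <- yellow(b2)
    if (abs(y1 - y2) > 1) {
      if (y1 > y2) return(list(tip = end2, base = end1, rule = "color"))
      return(list(tip = end1, base = end2, rule = "color"))
    }
  }
  # geometric fallback: blunter (larger) end band is the base
  if (sum(b1) >= sum(b2)) {
    list(tip = end2, base = end1, rule = "geometry")
  } else {
    list(tip = end1, base = end2, rule = "geometry")
  }
}

#' Measure kernel width perpendicular to the tip-center axis
#'
#' Finds the contour point P forming an angle of 90 degrees (within
#' `angle_tol`) at the center of mass with the tip; among candidates the
#' one closest to exactly 90 degrees wins. The line from P through the
#' center is extended to its opposite contour intersection, and the width
#' is the distance between the two intersection points.
#'
#' @param contour n x 2 contour matrix.
#' @param center Center of mass (mean of contour coordinates).
#' @param tip Tip coordinates.
#' @param angle_tol Angular tolerance in degrees (default 5).
#' @return List with `width`, `p1`, `p2` (the width points) and
#'   `obtainable`; when no contour point satisfies the tolerance the kernel
#'   is flagged `obtainable = FALSE` (removed downstream).
#' @export
measure_width <- function(contour, center, tip, angle_tol = 5) {
  vt <- tip - center
  nt <- sqrt(sum(vt^2))
  vp <- sweep(contour, 2, center)
  np <- sqrt(rowSums(vp^2))
  ok <- np > 1e-9 & nt > 1e-9
  cosang <- (vp[, 1] * vt[1] + vp[, 2] * vt[2]) / (np * nt)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  dev <- abs(ang - 90)
  dev[!ok] <- Inf
  if (min(dev) > angle_tol) {
    return(list(width = NA_real_, p1 = NULL, p2 = NULL, obtainable = FALSE))
  }
  i <- which.min(dev)
  p1 <- contour[i, ]
  u <- (center - p1) / sqrt(sum((center - p1)^2))
  proj <- vp[, 1] * u[1] + vp[, 2] * u[2]
  perp <- abs(vp[, 1] * u[2] - vp[, 2] * u[1])
  cand <- which(proj > 0)
  if (length(cand) == 0) {
    return(list(width = NA_real_, p1 = p1, p2 = NULL, obtainable = FALSE))
  }
  near <- cand[perp[cand] <= 1.5]
  j <- if (length(near) > 0) near[which.max(proj[near])] else cand[which.min(perp[cand])]
  p2 <- contour[j, ]
  list(width = sqrt(sum((p1 - p2)^2)), p1 = p1, p2 = p2, obtainable = TRUE)
}

#' Axial color-sampling region of a kernel
#'
#' Projects every kernel pixel onto the tip-to-base axis (tip = 0,
#' base = 1) and keeps pixels with normalized position in
#' `[cut_tip, 1 - cut_base]`. With the defaults this is the band [0.30,
#' 0.85]: the basal 15% (yellow endosperm cap) and the 30% nearest the tip
#' are excluded so the sampled color reflects the pericarp body.
#'
#' @param mask Binary component mask (width x height).
#' @param tip,base Landmark coordinates (must differ).
#' @param cut_tip,cut_base Excluded axial fractions (defaults 0.30, 0.15).
#' @return List with `region` (binary matrix subset of `mask`) and
#'   `n_pixels`; an empty region flags the kernel for removal.
#' @export
axial_region_mask <- function(mask, tip, base, cut_tip = 0.30,
                              cut_base = 0.15) {
  stopifnot(!all(tip == base))
  pix <- which(mask > 0, arr.ind = TRUE)
  axis <- base - tip
  tt <- ((pix[, 1] - tip[1]) * axis[1] + (pix[, 2] - tip[2]) * axis[2]) /
    sum(axis^2)
  keep <- tt >= cut_tip & tt <= 1 - cut_base
  region <- matrix(0L, nrow(mask), ncol(mask))
  region[pix[keep, , drop = FALSE]] <- 1L
  list(region = region, n_pixels = sum(keep))
}

#' Landmark and color-sample every kernel in a labeled mask
#'
#' Runs the per-kernel geometry chain (contour, tip/base, width, axial
#' region) and samples the mean region RGB and hue, recording the removal
#' reason for every kernel that fails a geometric quality check.
#'
#' @param labeled A `labeled_mask` from [split_components()].
#' @param image The RGB array the mask came from.
#' @param image_id Identifier recorded in the output (default "img").
#' @param min_contour_points,angle_tol,cut_tip,cut_base Geometry
#'   parameters.
#' @return List with `kernels` (data frame: kernel_id, image_id, length_px,
#'   width_px, lw_ratio, mean_r/g/b, hue, achromatic, n_region_pixels) and
#'   `removed` (data frame: kernel_id, reason).
#' @export
analyze_kernels <- function(labeled, image, image_id = "img",
                            min_contour_points = 100, angle_tol = 5,
                            cut_tip = 0.30, cut_base = 0.15) {
  stopifnot(inherits(labeled, "labeled_mask"))
  keep <- list(); removed <- list()
  for (k in seq_len(labeled$n_components)) {
    mask <- (labeled$labels == k) * 1L
    if (sum(mask) == 0) next
    ctr <- trace_contour(mask, min_points = min_contour_points)
    if (!ctr$retained) {
      removed[[length(removed) + 1]] <- data.frame(kernel_id = k, reason = "contour_points")
      next
    }
    ends <- locate_tip_base(ctr$xy)
    ori <- orient_tip_base(mask, ends$end1, ends$end2, image = image)
    center <- colMeans(ctr$xy)
    wd <- measure_width(ctr$xy, center, ori$tip, angle_tol = angle_tol)
    if (!wd$obtainable || wd$width <= 0) {
      removed[[length(removed) + 1]] <- data.frame(kernel_id = k, reason = "width")
      next
    }
    reg <- axial_region_mask(mask, ori$tip, ori$base, cut_tip = cut_tip,
                             cut_base = cut_base)
    if (reg$n_pixels == 0) {
      removed[[length(removed) + 1]] <- data.frame(kernel_id = k, reason = "empty_region")
      next
    }
    sel <- which(reg$region > 0)
    mr <- mean(image[, , 1][sel]); mg <- mean(image[, , 2][sel])
    mb <- mean(image[, , 3][sel])
    h <- kernel_hue(mr, mg, mb)
    keep[[length(keep) + 1]] <- data.frame(
      kernel_id = k, image_id = image_id, length_px = ends$length,
      width_px = wd$width, lw_ratio = ends$length / wd$width,
      mean_r = mr, mean_g = mg, mean_b = mb,
      hue = h$hue, achromatic = h$achromatic,
      n_region_pixels = reg$n_pixels, stringsAsFactors = FALSE)
  }
  list(kernels = if (length(keep)) do.call(rbind, keep) else
         data.frame(kernel_id = integer(0)),
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(kernel_id = integer(0), reason = character(0)))
}
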
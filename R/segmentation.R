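#' Mean-RGB luminance of an image
#'
#' @param image Width x height x 3 array with 8-bit channels.
#' @return Width x height matrix of luminance values in [0, 1], the mean of
#'   the three channels scaled by 255.
#' @export
luminance <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  (image[, , 1] + image[, , 2] + image[, , 3]) / 3 / 255
}

#' Trend-corrected binarization threshold
#'
#' Fits a linear illumination trend, luminance ~ x + y, on a random pixel
#' subsample, then finds a global Otsu threshold on the trend-corrected
#' residuals. The returned threshold surface (fitted plane plus the scalar
#' Otsu offset) separates foreground from background even under a smooth
#' illumination gradient.
#'
#' @param gray Width x height luminance matrix in [0, 1].
#' @param n_subsamples Pixels to subsample for the trend fit (default 3000,
#'   capped at the pixel count).
#' @param seed Seed for the subsample (default 0).
#' @return List with `surface` (matrix, same size as `gray`), `offset` (the
#'   scalar residual threshold), `coef` (plane coefficients) and
#'   `degenerate` (TRUE for a constant image, where the global value is
#'   returned with a warning flag).
#' @export
compute_trend_threshold <- function(gray, n_subsamples = 3000, seed = 0) {
  stopifnot(is.matrix(gray), all(gray >= 0 & gray <= 1))
  W <- nrow(gray); H <- ncol(gray)
  n_subsamples <- min(n_subsamples, W * H)
  set.seed(seed)
  idx <- sample.int(W * H, n_subsamples)
  xs <- ((idx - 1) %% W) + 1
  ys <- ((idx - 1) %/% W) + 1
  fit <- stats::lm(l ~ x + y, data = data.frame(l = gray[idx], x = xs, y = ys))
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  plane <- cf[1] + outer(cf[2] * seq_len(W), cf[3] * seq_len(H), "+")
  resid <- gray - plane
  if (stats::sd(resid) < 1e-8 || diff(range(resid)) < 1e-8) {
    return(list(surface = plane, offset = 0, coef = cf, degenerate = TRUE))
  }
  r01 <- (resid - min(resid)) / diff(range(resid))
  t01 <- EBImage::otsu(EBImage::Image(r01), range = c(0, 1))
  offset <- t01 * diff(range(resid)) + min(resid)
  list(surface = plane + offset, offset = offset, coef = cf,
       degenerate = FALSE)
}

#' Binarize a luminance image and clean the mask
#'
#' Foreground pixels must exceed both the minimum luminance and the trend
#' threshold. The mask is then cleaned by a morphological opening (removes
#' speckles), hole filling by closing plus hull fill, and a final opening
#' that removes residual debris. The `clean_size` / `fill_size` /
#' `final_clean` defaults of 1, 7 and 5 are structuring-element radii in
#' pixels (a size-k step uses a disc brush of diameter 2k + 1).
#'
#' @param gray Width x height luminance matrix in [0, 1].
#' @param threshold Threshold surface (matrix) or scalar, e.g. from
#'   [compute_trend_threshold()].
#' @param min_luminance Fixed lower luminance bound (default 0.4).
#' @param clean_size,fill_size,final_clean Structuring-element sizes for the
#'   three cleaning steps.
#' @return Binary width x height matrix (0/1). An empty foreground is a
#'   valid result.
#' @export
binarize_and_clean <- function(gray, threshold, min_luminance = 0.4,
                               clean_size = 1, fill_size = 7,
                               final_clean = 5) {
  if (is.matrix(threshold)) stopifnot(all(dim(threshold) == dim(gray)))
  fg <- (gray > threshold) & (gray > min_luminance)
  m <- EBImage::Image(fg * 1)
  brush <- function(k) EBImage::makeBrush(2 * k + 1, shape = "disc")
  if (clean_size > 0) m <- EBImage::opening(m, brush(clean_size))
  if (fill_size > 0) {
    m <- EBImage::closing(m, brush(fill_size))
    m <- EBImage::fillHull(m)
  }
  if (final_clean > 0) m <- EBImage::opening(m, brush(final_clean))
  out <- EBImage::imageData(m)
  storage.mode(out) <- "integer"
  out
}

#' Label connected foreground components, splitting touching kernels
#'
#' Components are labeled on the binary mask; when `use_watershed` is set,
#' a distance-transform watershed separates kernels that touch through a
#' thin neck before labeling. Labeling is 4-connected (recorded in the
#' result).
#'
#' @param mask Binary width x height matrix.
#' @param use_watershed Split touching objects by watershed (default TRUE).
#' @return List of class `labeled_mask`: `labels` (integer matrix, 0 =
#'   background), `n_components`, `connectivity` (4).
#' @export
split_components <- function(mask, use_watershed = TRUE) {
  m <- EBImage::Image(mask * 1)
  labels <- if (use_watershed && any(mask > 0)) {
    EBImage::watershed(EBImage::distmap(m), tolerance = 1)
  } else {
    EBImage::bwlabel(m)
  }
  lab <- EBImage::imageData(labels)
  storage.mode(lab) <- "integer"
  structure(list(labels = lab, n_components = max(lab), connectivity = 4L),
            class = "labeled_mask")
}

#' Segment a kernel-scan image end to end
#'
#' Convenience wrapper: luminance, trend threshold, binarize/clean, split.
#'
#' @param image Width x height x 3 RGB array (0-255).
#' @param min_luminance,clean_size,fill_size,final_clean,use_watershed
#'   Passed to the component steps.
#' @param n_subsamples,seed Passed to [compute_trend_threshold()].
#' @return List with `labeled` (a `labeled_mask`), `threshold` and `gray`.
#' @export
segment_scan <- function(image, min_luminance = 0.4, clean_size = 1,
                         fill_size = 7, final_clean = 5,
                         use_watershed = TRUE, n_subsamples = 3000,
                         seed = 0) {
  gray <- luminance(image)
  thr <- compute_trend_threshold(gray, n_subsamples = n_subsamples,
                                 seed = seed)
  mask <- binarize_and_clean(gray, thr$surface,
                             min_luminance = min_luminance,
                             clean_size = clean_size, fill_size = fill_size,
                             final_clean = final_clean)
  list(labeled = split_components(mask, use_watershed = use_watershed),
       threshold = thr, gray = gray)
}
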
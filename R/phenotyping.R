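#' Hue of a mean RGB color
#'
#' Standard RGB-to-HSV hue on channel means, scaled to degrees in
#' [0, 360). Achromatic input (R = G = B), where hue is undefined, returns
#' 0 with a flag. Vectorized over triples.
#'
#' @param r,g,b Channel means in [0, 255].
#' @return List with `hue` (degrees) and `achromatic` (logical).
#' @export
kernel_hue <- function(r, g, b) {
  stopifnot(all(r >= 0 & r <= 255), all(g >= 0 & g <= 255),
            all(b >= 0 & b <= 255))
  h <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)[1, ] * 360
  achromatic <- (pmax(r, g, b) - pmin(r, g, b)) == 0
  h[achromatic] <- 0
  list(hue = unname(h), achromatic = unname(achromatic))
}

# IQR fence filter shared by the shape and color QC steps; IQR = 0 passes
# everything (identical values are not outliers)
.iqr_keep <- function(x, mult) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(rep(TRUE, length(x)))
  x >= q[1] - mult * iqr & x <= q[2] + mult * iqr
}

#' Shape quality control within one image
#'
#' Removes kernels whose length-to-width ratio lies outside the
#' `iqr_mult` x IQR fences of that image's ratios. With fewer than 4
#' kernels the IQR is meaningless and all kernels pass with a warning.
#'
#' @param kernels Kernel table for one image (needs `lw_ratio`).
#' @param iqr_mult Fence multiplier (default 1.5).
#' @return List with `kernels` (retained rows), `removed` (dropped rows)
#'   and `warning` (TRUE when the filter was skipped for lack of kernels).
#' @export
shape_qc <- function(kernels, iqr_mult = 1.5) {
  if (nrow(kernels) < 4) {
    warning("fewer than 4 kernels: shape QC skipped")
    return(list(kernels = kernels,
                removed = kernels[0, , drop = FALSE], warning = TRUE))
  }
  keep <- .iqr_keep(kernels$lw_ratio, iqr_mult)
  list(kernels = kernels[keep, , drop = FALSE],
       removed = kernels[!keep, , drop = FALSE], warning = FALSE)
}

#' Color quality control across all kernels
#'
#' Pools kernels across lines and removes any kernel whose mean R, G or B
#' falls outside the pooled `iqr_mult` x IQR fences of that channel. Set
#' semantics: the retained set does not depend on row order.
#'
#' @param kernels Pooled kernel table (needs `mean_r`, `mean_g`, `mean_b`).
#' @param iqr_mult Fence multiplier (default 1.5).
#' @return List with `kernels` (retained) and `removed`.
#' @export
color_qc <- function(kernels, iqr_mult = 1.5) {
  keep <- .iqr_keep(kernels$mean_r, iqr_mult) &
    .iqr_keep(kernels$mean_g, iqr_mult) &
    .iqr_keep(kernels$mean_b, iqr_mult)
  list(kernels = kernels[keep, , drop = FALSE],
       removed = kernels[!keep, , drop = FALSE])
}

#' Aggregate retained kernels to line x replicate hue records
#'
#' Per-image hue is the mean over that image's retained kernels; the line x
#' replicate phenotype is the mean over the plot's image(s). Images with no
#' retained kernels are excluded with a logged reason.
#'
#' @param kernels Retained kernel table (needs `image_id`, `hue`).
#' @param metadata Data frame mapping `image_id` to `line_id` and
#'   `replicate`.
#' @return List with `lines` (data frame: line_id, replicate, hue,
#'   n_kernels), `images` (per-image means) and `excluded` (image ids with
#'   zero retained kernels).
#' @export
aggregate_line_hue <- function(kernels, metadata) {
  stopifnot(all(c("image_id", "hue") %in% names(kernels)),
            all(c("image_id", "line_id", "replicate") %in% names(metadata)))
  unknown <- setdiff(kernels$image_id, metadata$image_id)
  if (length(unknown) > 0) {
    stop("kernels from unmapped image(s): ", paste(unknown, collapse = ", "))
  }
  imgs <- stats::aggregate(hue ~ image_id, data = kernels, FUN = mean)
  imgs$n_kernels <- stats::aggregate(hue ~ image_id, data = kernels,
                                     FUN = length)$hue
  excluded <- setdiff(metadata$image_id, imgs$image_id)
  merged <- merge(imgs, metadata, by = "image_id")
  lines <- stats::aggregate(hue ~ line_id + replicate, data = merged,
                            FUN = mean)
  lines$n_kernels <- stats::aggregate(n_kernels ~ line_id + replicate,
                                      data = merged, FUN = sum)$n_kernels
  list(lines = lines[order(lines$line_id, lines$replicate), ],
       images = merged, excluded = excluded)
}

#' Threshold-on-hue helper classifier for binary pigment class
#'
#' The binary pigmented/clear class is normally an input scored by eye;
#' this helper classifies lines as pigmented when their hue falls below a
#' threshold. It is provided for simulations and never substituted
#' silently for visual scores.
#'
#' @param hue Numeric hue values (degrees).
#' @param threshold Hue below which a line is called pigmented.
#' @return Integer vector of 0/1 pigment classes.
#' @export
classify_pigment <- function(hue, threshold) {
  as.integer(hue < threshold)
}
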
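#' Discretize ROI intensities with a fixed bin width
#'
#' In-mask intensities are binned as
#' `level = floor((v - min(v_ROI)) / bin_width) + 1`, i.e. relative binning
#' anchored at the ROI minimum. The anchor is taken per image, so filtered
#' images with arbitrary signed ranges discretize the same way as the
#' original. Levels are consecutive integers starting at 1; voxels outside
#' the mask carry level 0.
#'
#' @param vol An `image_volume`.
#' @param mask A `binary_mask` sharing `vol`'s geometry and non-empty.
#' @param bin_width Intensity bin width (> 0); the study default is 25.
#' @return A `quantized_roi`: list with `levels` (integer array cropped to
#'   the mask bounding box, 0 outside the ROI), `n_levels`, `bin_width`,
#'   `roi_min`, and `values` (the raw in-mask intensities).
#' @export
discretize <- function(vol, mask, bin_width = 25) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "binary_mask"))
  stopifnot_same_geometry(vol, mask, "image and mask")
  if (!sum(mask$indicator))
    stop("cannot discretize an empty mask", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive", call. = FALSE)
  bb <- mask_bbox(mask$indicator)
  ind <- mask$indicator[bb$x, bb$y, bb$z, drop = FALSE]
  vals3 <- vol$values[bb$x, bb$y, bb$z, drop = FALSE]
  v <- vals3[ind]
  lv <- array(0L, dim(ind))
  lv[ind] <- as.integer(floor((vals3[ind] - min(v)) / bin_width)) + 1L
  structure(list(levels = lv, n_levels = max(lv), bin_width = bin_width,
                 roi_min = min(v), values = v, spacing = mask$spacing),
            class = "quantized_roi")
}

mask_bbox <- function(ind) {
  w <- which(ind, arr.ind = TRUE)
  list(x = min(w[, 1]):max(w[, 1]),
       y = min(w[, 2]):max(w[, 2]),
       z = min(w[, 3]):max(w[, 3]))
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d voxels, %d gray levels (bin width %g)\n",
              length(x$values), x$n_levels, x$bin_width))
  invisible(x)
}
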
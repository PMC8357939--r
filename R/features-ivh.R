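#' Intensity-volume histogram features (22 features)
#'
#' Features of the cumulative intensity-volume curve of the in-mask voxels.
#' With `nu(theta)` the fraction of ROI volume at intensity `>= theta`:
#' * `ivh_i10` ... `ivh_i90`: `I_x`, the minimum intensity of the hottest
#'   `x`% of the volume (deciles of `x`), i.e. the intensity at volume
#'   fraction `x`.
#' * `ivh_v10` ... `ivh_v90`: `V_x`, the volume fraction at relative
#'   intensity `x`%, where the threshold is `min + x/100 * (max - min)`.
#' * `ivh_vabs_0`, `ivh_vabs_25`, `ivh_vabs_50`, `ivh_vabs_75`: volume
#'   fraction at the absolute intensity thresholds 0, 25, 50, 75 (intensity
#'   units of the image the ROI was taken from).
#'
#' `I_x` is nonincreasing in `x` and `V_x` is nonincreasing in `x`. On a
#' constant ROI every `I_x` equals the constant and every relative `V_x` is 1.
#'
#' @param vol An `image_volume`.
#' @param mask A non-empty `binary_mask` sharing `vol`'s geometry.
#' @return Named numeric vector of 22 features (prefix `ivh_`).
#' @export
ivh_features <- function(vol, mask) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "binary_mask"))
  stopifnot_same_geometry(vol, mask, "image and mask")
  if (!sum(mask$indicator)) stop("empty mask", call. = FALSE)
  v <- sort(vol$values[mask$indicator], decreasing = TRUE)
  n <- length(v)
  xs <- seq(10, 90, by = 10)
  ix <- v[pmin(n, pmax(1L, ceiling(xs / 100 * n)))]
  rng <- max(v) - min(v)
  vx <- vapply(xs, function(x) {
    theta <- min(v) + x / 100 * rng
    mean(v >= theta)
  }, numeric(1))
  vabs <- vapply(c(0, 25, 50, 75), function(theta) mean(v >= theta), numeric(1))
  stats::setNames(c(ix, vx, vabs),
                  c(paste0("ivh_i", xs), paste0("ivh_v", xs),
                    paste0("ivh_vabs_", c(0, 25, 50, 75))))
}
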
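#' First-order intensity statistics (24 features)
#'
#' Intensity statistics of the in-mask voxels: location, spread, histogram
#' shape, and energy measures. `entropy` and `uniformity` are computed on
#' the fixed-bin-width discretized histogram (same rule as [discretize()]).
#' Skewness and kurtosis use population moments; kurtosis is not
#' excess-corrected. Degenerate conventions: on a constant ROI,
#' skewness, kurtosis and entropy are 0 and uniformity is 1; ratio features
#' with a zero denominator return 0.
#'
#' @param vol An `image_volume`.
#' @param mask A non-empty `binary_mask` sharing `vol`'s geometry.
#' @param bin_width Bin width for the histogram-based features.
#' @return Named numeric vector of 24 features (prefix `fo_`).
#' @export
first_order_features <- function(vol, mask, bin_width = 25) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "binary_mask"))
  stopifnot_same_geometry(vol, mask, "image and mask")
  if (!sum(mask$indicator)) stop("empty mask", call. = FALSE)
  v <- vol$values[mask$indicator]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  sk <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  rng <- v[v >= q[1] & v <= q[5]]
  lev <- floor((v - min(v)) / bin_width)
  p <- tabulate(lev + 1L) / n
  p <- p[p > 0]
  safe_div <- function(a, b) if (abs(b) < .Machine$double.eps) 0 else a / b
  c(fo_mean = mu,
    fo_median = q[3],
    fo_minimum = min(v),
    fo_maximum = max(v),
    fo_range = max(v) - min(v),
    fo_variance = m2,
    fo_standard_deviation = sqrt(m2),
    fo_skewness = sk,
    fo_kurtosis = ku,
    fo_percentile10 = q[1],
    fo_percentile25 = q[2],
    fo_percentile75 = q[4],
    fo_percentile90 = q[5],
    fo_interquartile_range = q[4] - q[2],
    fo_mean_absolute_deviation = mean(abs(v - mu)),
    fo_median_absolute_deviation = mean(abs(v - q[3])),
    fo_robust_mean_absolute_deviation = mean(abs(rng - mean(rng))),
    fo_energy = sum(v^2),
    fo_total_energy = sum(v^2) * voxel_volume_mm3(vol),
    fo_root_mean_square = sqrt(mean(v^2)),
    fo_entropy = -sum(p * log2(p)),
    fo_uniformity = sum(p^2),
    fo_coefficient_of_variation = safe_div(sqrt(m2), mu),
    fo_quartile_coefficient_of_dispersion = safe_div(q[4] - q[2], q[4] + q[2]))
}
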
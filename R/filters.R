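# Image filters used before feature extraction: Laplacian of Gaussian and a
# single-level undecimated separable 3D wavelet transform. Both are applied
# with replicate (edge-clamped) boundary handling via per-axis weight
# matrices, sharing the separable machinery of resample.R.

# Convolution matrix for a 1D tap vector with given integer offsets,
# replicate padding at the ends.
axis_filter_matrix <- function(n, taps, offsets) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ks <- pmin(pmax(i - 1L + offsets, 0L), n - 1L)
    for (m in seq_along(ks)) W[i, ks[m] + 1L] <- W[i, ks[m] + 1L] + taps[m]
  }
  W
}

gauss_taps <- function(sigma_vox, spacing) {
  r <- max(1L, ceiling(4 * sigma_vox))
  t <- (-r:r) * spacing  # physical coordinate, mm
  s <- sigma_vox * spacing
  g <- exp(-t^2 / (2 * s^2))
  g0 <- g / sum(g)
  # second derivative of the Gaussian, in mm^-2, zero-mean so that the
  # response to a constant image is exactly zero
  g2 <- g0 * (t^2 - s^2) / s^4
  g2 <- g2 - mean(g2)
  list(g = g0, g2 = g2, offsets = -r:r)
}

#' Laplacian-of-Gaussian filter
#'
#' 3D Laplacian-of-Gaussian response computed as the sum of the three
#' separable second-derivative convolutions. The scale `sigma` is a physical
#' length in mm and is converted per-axis through the voxel spacing, so the
#' response is isotropic in physical units even on anisotropic grids.
#'
#' @param vol An `image_volume`.
#' @param sigma Gaussian scale in mm (> 0).
#' @return An `image_volume` of the same geometry holding the filter
#'   response (units: intensity per mm^2).
#' @export
log_filter <- function(vol, sigma) {
  stopifnot(inherits(vol, "image_volume"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number (mm)", call. = FALSE)
  d <- dim(vol$values)
  tp <- lapply(1:3, function(ax) gauss_taps(sigma / vol$spacing[ax], vol$spacing[ax]))
  Wg <- lapply(1:3, function(ax)
    axis_filter_matrix(d[ax], tp[[ax]]$g, tp[[ax]]$offsets))
  W2 <- lapply(1:3, function(ax)
    axis_filter_matrix(d[ax], tp[[ax]]$g2, tp[[ax]]$offsets))
  out <- apply_separable(vol$values, list(W2[[1]], Wg[[2]], Wg[[3]])) +
    apply_separable(vol$values, list(Wg[[1]], W2[[2]], Wg[[3]])) +
    apply_separable(vol$values, list(Wg[[1]], Wg[[2]], W2[[3]]))
  image_volume(out, spacing = vol$spacing, origin = vol$origin)
}

# Decomposition filter taps. Coiflet-1 is the default family; Haar is kept
# for tests because its short orthonormal taps make hand-checks easy.
wavelet_taps <- function(family = c("coif1", "haar")) {
  family <- match.arg(family)
  if (family == "haar") {
    lo <- c(1, 1) / sqrt(2)
    hi <- c(-1, 1) / sqrt(2)
  } else {
    lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
            0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
    hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
            0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  }
  n <- length(lo)
  # center the support around 0
  offsets <- seq_len(n) - 1L - (n %/% 2L)
  list(lo = lo, hi = hi, offsets = offsets)
}

#' Wavelet subband labels in (x, y, z) order
#' @return Character vector of the 8 subband labels.
#' @export
wavelet_subbands <- function() {
  c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Separable single-level stationary (undecimated) wavelet transform: each
#' axis is convolved with either the low-pass (L) or high-pass (H)
#' decomposition filter, producing 8 subbands with the same grid as the
#' input. Subband labels give the filter per axis in (x, y, z) order, so
#' "HLL" is high-pass along x and low-pass along y and z. Boundaries use
#' replicate padding.
#'
#' @param vol An `image_volume` with at least as many voxels per axis as the
#'   filter length.
#' @param family Wavelet family: `"coif1"` (default) or `"haar"`.
#' @return Named list of 8 `image_volume`s (`LLL` ... `HHH`).
#' @export
wavelet_decompose <- function(vol, family = "coif1") {
  stopifnot(inherits(vol, "image_volume"))
  tp <- wavelet_taps(family)
  d <- dim(vol$values)
  if (any(d < length(tp$lo)))
    stop(sprintf("volume (%s) smaller than the %s filter support (%d taps)",
                 paste(d, collapse = "x"), family, length(tp$lo)),
         call. = FALSE)
  Wlo <- lapply(1:3, function(ax) axis_filter_matrix(d[ax], tp$lo, tp$offsets))
  Whi <- lapply(1:3, function(ax) axis_filter_matrix(d[ax], tp$hi, tp$offsets))
  out <- lapply(wavelet_subbands(), function(lab) {
    ax <- strsplit(lab, "")[[1]]
    Ws <- lapply(1:3, function(a) if (ax[a] == "L") Wlo[[a]] else Whi[[a]])
    image_volume(apply_separable(vol$values, Ws),
                 spacing = vol$spacing, origin = vol$origin)
  })
  names(out) <- wavelet_subbands()
  out
}
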
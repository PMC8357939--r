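# Phantom generation: a smooth random blob (a sphere modulated by a
# low-order random directional field) embedded in a textured low-contrast
# background, emulating a poorly conspicuous abdominal tumor on contrast CT.

# Low-order smooth directional basis on the unit sphere (degree <= 2
# spherical-harmonic-like polynomials in the direction cosines).
blob_basis <- function(u) {
  cbind(u[, 1], u[, 2], u[, 3],
        sqrt(3) * u[, 1] * u[, 2],
        sqrt(3) * u[, 1] * u[, 3],
        sqrt(3) * u[, 2] * u[, 3],
        (3 * u[, 3]^2 - 1) / 2,
        sqrt(3) / 2 * (u[, 1]^2 - u[, 2]^2))
}

# Deterministic quasi-uniform directions (Fibonacci sphere), used to
# calibrate the blob radius so the enclosed volume matches the target.
fibonacci_sphere <- function(n = 500) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate one phantom patient: image plus ground-truth tumor mask
#'
#' Draws a tumor volume from the configured distribution (normal, truncated
#' to `[15, 100]` cm^3), shapes a smooth random blob with that volume,
#' rasterizes it on the native anisotropic grid, and embeds it in a textured
#' background: a constant soft-tissue level plus a mild linear intensity
#' gradient, spatially correlated (Gaussian-smoothed) texture, white
#' Gaussian noise, and the configured tumor contrast added inside the mask.
#' The blob center is jittered uniformly within one voxel so that voxel-
#' center rasterization is volume-unbiased in expectation.
#'
#' @param config A [cohort_config()].
#' @param patient_seed Integer seed for this patient (see
#'   [derive_seed()] for the cohort splitting rule).
#' @return List with `image` (`image_volume`) and `truth` (`binary_mask`).
#' @export
generate_phantom <- function(config, patient_seed) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(as.integer(patient_seed), {
    truth <- phantom_mask(config)
    image <- phantom_image(config, truth)
  })
  list(image = image, truth = truth)
}

# Rasterized ground-truth blob only (used on its own in calibration checks).
phantom_mask <- function(config) {
  sp <- config$native_spacing
  dims <- pmax(4L, as.integer(ceiling(config$fov_mm / sp)))
  target_cm3 <- min(100, max(15, stats::rnorm(1, config$tumor_volume_mean,
                                              config$tumor_volume_sd)))
  amp <- config$blob_perturb_amp
  coef <- stats::rnorm(8, 0, amp / sqrt(8) * 2)
  quad <- fibonacci_sphere(500)
  pq <- pmax(-0.5, blob_basis(quad) %*% coef)
  m3 <- mean((1 + pq)^3)
  r0 <- (3 * target_cm3 * 1000 / (4 * pi * m3))^(1 / 3)
  center <- (dims - 1) * sp / 2 + stats::runif(3, -0.5, 0.5) * sp
  rmax <- r0 * (1 + max(pq)) + 2 * max(sp)
  if (any(center - rmax < -sp / 2) || any(center + rmax > (dims - 0.5) * sp))
    stop(sprintf("tumor (%.1f cm^3) does not fit the %s mm field of view",
                 target_cm3, paste(config$fov_mm, collapse = "x")),
         call. = FALSE)
  # restrict rasterization to the bounding box of the maximal radius
  lo <- pmax(1L, as.integer(floor((center - rmax) / sp)) + 1L)
  hi <- pmin(dims, as.integer(ceiling((center + rmax) / sp)) + 1L)
  gx <- (lo[1]:hi[1] - 1) * sp[1] - center[1]
  gy <- (lo[2]:hi[2] - 1) * sp[2] - center[2]
  gz <- (lo[3]:hi[3] - 1) * sp[3] - center[3]
  nb <- c(length(gx), length(gy), length(gz))
  X <- array(gx, nb)
  Y <- array(rep(gy, each = nb[1]), nb)
  Z <- array(rep(gz, each = nb[1] * nb[2]), nb)
  d <- sqrt(X^2 + Y^2 + Z^2)
  d[d == 0] <- 1e-9
  u <- cbind(c(X / d), c(Y / d), c(Z / d))
  rdir <- r0 * pmax(0.5, 1 + blob_basis(u) %*% coef)
  inside <- array(c(d) <= rdir, nb)
  ind <- array(FALSE, dims)
  ind[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- inside
  binary_mask(ind, spacing = sp)
}

phantom_image <- function(config, truth) {
  dims <- grid_dim(truth)
  sp <- truth$spacing
  vals <- array(config$background_level, dims)
  if (config$gradient_amp > 0) {
    gdir <- stats::rnorm(3)
    gdir <- gdir / sqrt(sum(gdir^2))
    gx <- (seq_len(dims[1]) - 1) / max(1, dims[1] - 1) - 0.5
    gy <- (seq_len(dims[2]) - 1) / max(1, dims[2] - 1) - 0.5
    gz <- (seq_len(dims[3]) - 1) / max(1, dims[3] - 1) - 0.5
    vals <- vals + config$gradient_amp *
      (array(gx * gdir[1], dims) +
       array(rep(gy * gdir[2], each = dims[1]), dims) +
       array(rep(gz * gdir[3], each = dims[1] * dims[2]), dims))
  }
  if (config$texture_sd > 0) {
    tex <- gauss_smooth(array(stats::rnorm(prod(dims)), dims),
                        sigma_mm = config$texture_corr_mm, spacing = sp)
    vals <- vals + tex * (config$texture_sd / stats::sd(tex))
  }
  vals <- vals + config$tumor_contrast * truth$indicator
  if (config$image_noise_sd > 0)
    vals <- vals + stats::rnorm(prod(dims), 0, config$image_noise_sd)
  image_volume(vals, spacing = sp)
}

# Separable Gaussian smoothing with replicate padding.
gauss_smooth <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  Ws <- lapply(1:3, function(ax) {
    tp <- gauss_taps(sigma_mm / spacing[ax], spacing[ax])
    axis_filter_matrix(d[ax], tp$g, tp$offsets)
  })
  apply_separable(arr, Ws)
}
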
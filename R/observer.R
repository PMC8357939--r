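# Simulated observer delineations. A contour error is modelled as a smooth
# random displacement of the true tumor surface (spatially correlated along
# the surface, as human contouring errors are) plus a global volume bias:
# the observer mask is a level set of the signed distance to the truth
# boundary minus a smooth directional noise field, with the level chosen so
# the delineated volume hits the (jittered) target volume.

#' Signed Euclidean distance to a mask boundary
#'
#' Anisotropic Euclidean distance transform (in mm): negative inside the
#' mask, positive outside, computed with a separable lower-envelope
#' algorithm.
#'
#' @param mask A `binary_mask`.
#' @return Numeric array of signed distances, same grid as the mask.
#' @keywords internal
signed_distance <- function(mask) {
  d <- grid_dim(mask)
  fg <- mask$indicator
  dout <- sqrt(cpp_edt_sq(c(fg), d[1], d[2], d[3], mask$spacing))
  din <- sqrt(cpp_edt_sq(c(!fg), d[1], d[2], d[3], mask$spacing))
  array(dout - din, d)
}

# Smooth directional (purely radial) random field: a random-cosine-feature
# Gaussian process on the unit sphere of directions around `center`. The
# correlation length is expressed as an arc length (mm) on a surface of
# radius `surf_r`. The field is sampled once on a lat-long direction grid
# (much finer than the correlation length) and bilinearly interpolated per
# voxel direction.
radial_noise_field <- function(u, surf_r, corr_mm, n_features = 32L,
                               nlat = 48L, nlon = 96L) {
  kappa <- surf_r / corr_mm
  w <- matrix(stats::rnorm(3L * n_features, 0, kappa), 3L, n_features)
  b <- stats::runif(n_features, 0, 2 * pi)
  th <- (seq_len(nlat) - 0.5) * pi / nlat
  phg <- (seq_len(nlon) - 1) * 2 * pi / nlon
  gu <- cbind(rep(sin(th), nlon) * rep(cos(phg), each = nlat),
              rep(sin(th), nlon) * rep(sin(phg), each = nlat),
              rep(cos(th), nlon))
  M <- gu %*% w + matrix(b, nrow(gu), n_features, byrow = TRUE)
  G <- sqrt(2 / n_features) * rowSums(cos(M))
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  ti <- theta / pi * nlat - 0.5
  pj <- phi / (2 * pi) * nlon
  t0 <- pmin(nlat - 1, pmax(0, floor(ti)))
  t1 <- pmin(nlat - 1, t0 + 1)
  ft <- pmin(1, pmax(0, ti - t0))
  p0 <- floor(pj) %% nlon
  p1 <- (p0 + 1) %% nlon
  fp <- pj - floor(pj)
  idx <- function(a, b) a + 1 + b * nlat
  (1 - ft) * (1 - fp) * G[idx(t0, p0)] + ft * (1 - fp) * G[idx(t1, p0)] +
    (1 - ft) * fp * G[idx(t0, p1)] + ft * fp * G[idx(t1, p1)]
}

#' Simulate one observer's delineation of a ground-truth mask
#'
#' The truth surface is displaced by a smooth random radial field with
#' standard deviation `boundary_noise_sd` (mm) and surface correlation
#' length `noise_corr_mm`, then uniformly dilated or eroded so the
#' delineated volume matches `volume_bias` times the truth volume (times a
#' lognormal per-delineation jitter with log-sd `volume_jitter_sd`, mean 1).
#'
#' @param truth Non-empty `binary_mask`.
#' @param profile One-row tibble as produced by [observer_profile()].
#' @param seed Integer seed for this (patient, observer) delineation.
#' @param noise_corr_mm Correlation length of the boundary noise along the
#'   surface, in mm.
#' @param sdist Optional precomputed [signed_distance()] of `truth`
#'   (recomputed when `NULL`); lets a caller simulating several observers of
#'   one patient share the transform.
#' @return A `binary_mask` on the truth grid.
#' @export
simulate_observer_mask <- function(truth, profile, seed, noise_corr_mm = 10,
                                   sdist = NULL) {
  stopifnot(inherits(truth, "binary_mask"))
  nvox <- sum(truth$indicator)
  if (!nvox) stop("ground-truth mask is empty", call. = FALSE)
  if (profile$volume_bias <= 0 || profile$boundary_noise_sd < 0)
    stop("invalid observer profile", call. = FALSE)
  d <- grid_dim(truth)
  sp <- truth$spacing
  if (is.null(sdist)) sdist <- signed_distance(truth)
  # The displacement can only flip membership within a band around the truth
  # surface; restrict all per-observer work to the truth bounding box plus a
  # margin that safely covers that band.
  band_r <- 5 * profile$boundary_noise_sd + 8
  bb <- mask_bbox(truth$indicator)
  mg <- ceiling((band_r + 5) / sp)
  bx <- max(1, min(bb$x) - mg[1]):min(d[1], max(bb$x) + mg[1])
  by <- max(1, min(bb$y) - mg[2]):min(d[2], max(bb$y) + mg[2])
  bz <- max(1, min(bb$z) - mg[3]):min(d[3], max(bb$z) + mg[3])
  sd_c <- sdist[bx, by, bz, drop = FALSE]
  dc <- dim(sd_c)
  withr::with_seed(as.integer(seed), {
    t_field <- sd_c
    if (profile$boundary_noise_sd > 0) {
      w <- which(truth$indicator, arr.ind = TRUE)
      center <- colMeans((w - 1) * rep(sp, each = nrow(w)))
      surf_r <- (3 * nvox * prod(sp) / (4 * pi))^(1 / 3)
      band <- which(abs(sd_c) <= band_r)
      bw <- arrayInd(band, dc)
      bw[, 1] <- bw[, 1] + bx[1] - 1L
      bw[, 2] <- bw[, 2] + by[1] - 1L
      bw[, 3] <- bw[, 3] + bz[1] - 1L
      rel <- (bw - 1) * rep(sp, each = nrow(bw)) -
        rep(center, each = nrow(bw))
      dn <- sqrt(rowSums(rel^2))
      dn[dn == 0] <- 1e-9
      u <- rel / dn
      psi <- radial_noise_field(u, surf_r, noise_corr_mm)
      psi <- psi * (profile$boundary_noise_sd / max(stats::sd(psi), 1e-12))
      t_field[band] <- t_field[band] - psi
    }
    jit <- profile$volume_jitter_sd
    mult <- if (jit > 0) exp(stats::rnorm(1, -jit^2 / 2, jit)) else 1
    target <- as.integer(round(nvox * profile$volume_bias * mult))
  })
  if (target < 1)
    stop(sprintf("observer %s: volume bias/jitter annihilates the mask",
                 profile$observer_id), call. = FALSE)
  if (target > length(t_field)) target <- length(t_field)
  b <- sort(c(t_field), partial = target)[target]
  sel <- array(t_field <= b, dc)
  if (!sum(sel))
    stop(sprintf("observer %s: perturbation annihilated the mask",
                 profile$observer_id), call. = FALSE)
  out <- array(FALSE, d)
  out[bx, by, bz] <- sel
  binary_mask(out, spacing = sp, origin = truth$origin)
}
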
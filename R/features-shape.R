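#' Shape features of a binary mask (17 features)
#'
#' Geometry descriptors of the (typically isotropically resampled) mask.
#' Surface area uses the voxel-face definition: the sum of the areas of
#' foreground voxel faces exposed to background or to the grid boundary.
#' This definition is exact for voxelized cuboids but overestimates the area
#' of smooth bodies, so derived sphericity/compactness values saturate below
#' their continuous ideals on rasterized spheres. Principal axis lengths are
#' `4 * sqrt(eigenvalue)` of the covariance of foreground voxel centers in
#' physical coordinates.
#'
#' @param mask A non-empty `binary_mask`.
#' @return Named numeric vector of 17 features (prefix `shape_`).
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  nvox <- sum(mask$indicator)
  if (!nvox) stop("empty mask", call. = FALSE)
  sp <- mask$spacing
  vv <- prod(sp)
  V <- nvox * vv
  A <- voxel_face_area(mask$indicator, sp)
  R <- (3 * V / (4 * pi))^(1 / 3)
  A_sphere <- 4 * pi * R^2
  w <- which(mask$indicator, arr.ind = TRUE)
  xyz <- sweep((w - 1), 2, sp, `*`)
  xyz <- sweep(xyz, 2, mask$origin, `+`)
  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  bb <- apply(xyz, 2, range)
  bbox_vol <- prod(bb[2, ] - bb[1, ] + sp)
  maxdiam <- max_surface_diameter(mask$indicator, sp)
  c(shape_voxel_count = as.numeric(nvox),
    shape_volume_mm3 = V,
    shape_surface_area_mm2 = A,
    shape_surface_to_volume_ratio = A / V,
    shape_sphericity = A_sphere / A,
    shape_compactness1 = V / (sqrt(pi) * A^1.5),
    shape_compactness2 = 36 * pi * V^2 / A^3,
    shape_spherical_disproportion = A / A_sphere,
    shape_asphericity = (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    shape_max_3d_diameter_mm = maxdiam,
    shape_major_axis_mm = 4 * sqrt(ev[1]),
    shape_minor_axis_mm = 4 * sqrt(ev[2]),
    shape_least_axis_mm = 4 * sqrt(ev[3]),
    shape_elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    shape_flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    shape_equivalent_diameter_mm = 2 * R,
    shape_extent = V / bbox_vol)
}

# Exposed-face surface area: faces between foreground and background (or the
# grid boundary), weighted by the physical face area per axis.
voxel_face_area <- function(ind, sp) {
  d <- dim(ind)
  face <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ind
  n <- 0
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  area <- 0
  for (s in shifts) {
    nb <- pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2], 2:(d[3] + 1) + s[3]]
    exposed <- ind & !nb
    ax <- which(s != 0)
    area <- area + sum(exposed) * face[ax]
  }
  area
}

# Largest pairwise distance between surface voxel centers.
max_surface_diameter <- function(ind, sp) {
  d <- dim(ind)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ind
  surf <- ind & !(pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
                  pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
                  pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
                  pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
                  pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
                  pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  w <- which(surf, arr.ind = TRUE)
  if (nrow(w) == 1) return(0)
  xyz <- sweep((w - 1), 2, sp, `*`)
  sqrt(max(as.numeric(stats::dist(xyz))^2))
}
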
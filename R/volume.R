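#' Construct a 3D image volume
#'
#' An `image_volume` is a 3D scalar grid (CT-number-like intensities) with a
#' physical geometry: per-axis voxel spacing in millimetres and the physical
#' position of the first voxel (the origin). Voxel indices are 0-based and the
#' physical position of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`;
#' axes are ordered (x, y, z).
#'
#' @param values 3D numeric array of intensities. All values must be finite.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin Numeric length-3, physical position (mm) of the first voxel.
#' @return An object of class `image_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @seealso [binary_mask()], [read_volume()], [resample_isotropic()]
#' @examples
#' vol <- image_volume(array(rnorm(4 * 4 * 4), c(4, 4, 4)), spacing = c(1, 1, 5))
#' dim(vol$values)
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("grid dimensions must all be >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` contains non-finite voxels", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary mask sharing an image volume's geometry
#'
#' @param indicator 3D logical (or 0/1 numeric) array marking foreground
#'   voxels.
#' @param spacing,origin Geometry as in [image_volume()]. Alternatively pass
#'   `geometry`, an `image_volume` or `binary_mask` to copy geometry from.
#' @param geometry Optional object to take `spacing`/`origin` from.
#' @return An object of class `binary_mask` with fields `indicator`,
#'   `spacing`, `origin`.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
#' msk <- binary_mask(m, spacing = c(5, 5, 5))
#' mask_volume_cm3(msk)
#' @export
binary_mask <- function(indicator, spacing = NULL, origin = NULL,
                        geometry = NULL) {
  if (!is.null(geometry)) {
    spacing <- geometry$spacing
    origin <- geometry$origin
  }
  if (is.null(origin)) origin <- c(0, 0, 0)
  if (!is.array(indicator) || length(dim(indicator)) != 3L)
    stop("`indicator` must be a 3D array", call. = FALSE)
  if (is.numeric(indicator)) {
    if (!all(indicator %in% c(0, 1)))
      stop("numeric `indicator` must contain only 0 and 1", call. = FALSE)
    indicator <- array(indicator != 0, dim(indicator))
  }
  if (!is.logical(indicator))
    stop("`indicator` must be logical or 0/1 numeric", call. = FALSE)
  if (anyNA(indicator))
    stop("`indicator` contains missing values", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers (mm)", call. = FALSE)
  structure(list(indicator = indicator, spacing = spacing, origin = origin),
            class = "binary_mask")
}

grid_dim <- function(x) {
  if (inherits(x, "image_volume")) dim(x$values) else dim(x$indicator)
}

#' Test whether two volumes/masks share a grid geometry
#'
#' @param a,b `image_volume` or `binary_mask` objects.
#' @param tol Relative tolerance on spacing and origin.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(a$spacing, b$spacing)) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin), abs(b$origin)))
}

stopifnot_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(sprintf("%s do not share grid geometry (dims/spacing/origin)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Voxel volume in mm^3
#' @param x An `image_volume` or `binary_mask`.
#' @return Scalar, product of the spacings (mm^3).
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Physical mask volume in cm^3
#' @param mask A `binary_mask`.
#' @return Foreground voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$indicator) * voxel_volume_mm3(mask) / 1000
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$indicator)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %s mm, %d foreground (%.2f cm^3)\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              sum(x$indicator), mask_volume_cm3(x)))
  invisible(x)
}
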
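#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a NIfTI-1 file into an [image_volume()]. The image must have exactly
#' three spatial dimensions (a trailing singleton fourth dimension is
#' tolerated and dropped). Only axis-aligned geometries are accepted: an
#' oblique rotation in the qform/sform is rejected rather than silently
#' resliced.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `image_volume`.
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
    attributes(img2)$dim <- d[1:3]
    vals <- img2
    d <- d[1:3]
  } else if (length(d) == 3L) {
    vals <- array(as.numeric(img), d)
  } else {
    stop(sprintf("%s: expected a 3D image, got %d dimensions", path, length(d)),
         call. = FALSE)
  }
  geo <- nifti_geometry(img, path)
  if (!all(is.finite(vals)))
    stop(sprintf("%s: image contains non-finite voxels", path), call. = FALSE)
  image_volume(vals, spacing = geo$spacing, origin = geo$origin)
}

nifti_geometry <- function(img, path) {
  xf <- RNifti::xform(img)
  code <- attr(xf, "code")
  pd <- RNifti::pixdim(img)[1:3]
  if (is.null(code) || code == 0) {
    return(list(spacing = as.numeric(pd), origin = c(0, 0, 0)))
  }
  rot <- xf[1:3, 1:3]
  offdiag <- rot - diag(diag(rot))
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop(sprintf("%s: oblique (non-axis-aligned) orientation is not supported",
                 path), call. = FALSE)
  if (any(diag(rot) <= 0))
    stop(sprintf("%s: flipped-axis orientation is not supported", path),
         call. = FALSE)
  list(spacing = as.numeric(diag(rot)), origin = as.numeric(xf[1:3, 4]))
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Floating-point grids are stored as 64-bit floats so that
#' `read_volume(write_volume(v))` reproduces `v` bit-exactly.
#'
#' @param vol An `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype, e.g. `"double"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "image_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop(sprintf("cannot write to %s", path), call. = FALSE)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  m <- structure(aff, code = 2L)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' @param path Path to a NIfTI file containing only 0/1 values.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  if (!all(vol$values %in% c(0, 1)))
    stop(sprintf("%s: mask file contains values other than 0/1", path),
         call. = FALSE)
  binary_mask(array(vol$values != 0, dim(vol$values)), geometry = vol)
}

#' Write a binary mask to a NIfTI-1 file as unsigned 8-bit 0/1
#'
#' @param mask A `binary_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  vol <- image_volume(array(as.numeric(mask$indicator), dim(mask$indicator)),
                      spacing = mask$spacing, origin = mask$origin)
  write_volume(vol, path, datatype = "uint8")
}
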
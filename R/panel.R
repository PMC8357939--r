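#' Feature extraction configuration
#'
#' Settings of the radiomic feature engine. Defaults reproduce the study
#' panel: isotropic resampling to 5 mm with windowed-sinc interpolation,
#' fixed bin width 25, texture matrices over the 13 symmetric 3D directions
#' at voxel offset 1, and the 10-image filter panel (original, Laplacian of
#' Gaussian, and the 8 undecimated 3D wavelet subbands), which yields exactly
#' 1277 named features per (image, mask) pair.
#'
#' @param target_spacing Isotropic voxel size in mm after resampling.
#' @param bin_width Discretization bin width in intensity units.
#' @param offset Voxel offset for GLCM co-occurrences.
#' @param filters Ordered character vector of filter labels; subset of
#'   `c("original", "LoG", wavelet_subbands())`.
#' @param log_sigma Laplacian-of-Gaussian scale in mm (default 5 mm, one
#'   voxel at the default target spacing).
#' @param wavelet_family Wavelet family for [wavelet_decompose()].
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(target_spacing = 5, bin_width = 25, offset = 1L,
                              filters = c("original", "LoG", wavelet_subbands()),
                              log_sigma = 5, wavelet_family = "coif1") {
  known <- c("original", "LoG", wavelet_subbands())
  if (anyDuplicated(filters) || !all(filters %in% known))
    stop("`filters` must be unique labels among: ",
         paste(known, collapse = ", "), call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (offset < 1) stop("`offset` must be >= 1", call. = FALSE)
  structure(list(target_spacing = target_spacing, bin_width = bin_width,
                 offset = as.integer(offset), filters = filters,
                 log_sigma = log_sigma, wavelet_family = wavelet_family),
            class = "extraction_config")
}

# All filtered images for one (already resampled) volume, as a named list.
filter_stack <- function(vol, config) {
  wanted <- config$filters
  stack <- list()
  if ("original" %in% wanted) stack$original <- vol
  if ("LoG" %in% wanted) stack$LoG <- log_filter(vol, config$log_sigma)
  wav <- intersect(wavelet_subbands(), wanted)
  if (length(wav)) {
    sub <- wavelet_decompose(vol, config$wavelet_family)
    stack <- c(stack, sub[wav])
  }
  stack[wanted]
}

# Features for one filtered image within one mask: first order, 4 texture
# families, IVH (126 features).
extract_filtered <- function(fvol, mask, config, filter_label) {
  q <- discretize(fvol, mask, config$bin_width)
  vals <- c(first_order_features(fvol, mask, config$bin_width),
            glcm_features(q, config$offset),
            glrlm_features(q),
            c(ngtdm_features(q), ngldm_features(q)),
            glszm_features(q),
            ivh_features(fvol, mask))
  cls <- c(rep("FirstOrder", 24), rep("GLCM", 26), rep("GLRLM", 16),
           rep("NGTDM_NGLDM", 22), rep("GLSZM", 16), rep("IVH", 22))
  tibble::tibble(filter = filter_label, feature_class = cls,
                 name = names(vals), value = unname(vals))
}

extract_from_stack <- function(stack, rmask, config) {
  rows <- purrr::imap(stack, function(fvol, lab)
    extract_filtered(fvol, rmask, config, lab))
  out <- dplyr::bind_rows(rows)
  if ("original" %in% names(stack)) {
    sv <- shape_features(rmask)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(filter = "original", feature_class = "Shape",
                     name = names(sv), value = unname(sv)))
  }
  out <- dplyr::mutate(out, feature_id = paste(.data$filter, .data$name, sep = "."))
  stopifnot(!anyDuplicated(out$feature_id))
  dplyr::select(out, "feature_id", "filter", "feature_class", "name", "value")
}

#' Extract the full radiomic feature panel for one image/mask pair
#'
#' Resamples the image (windowed sinc) and the mask (linear + 0.5 threshold)
#' to the isotropic target spacing, computes shape features once on the
#' resampled mask, then for every configured filter computes first-order,
#' GLCM, GLRLM, GLSZM, NGTDM/NGLDM and IVH features on the filtered,
#' discretized image restricted to the mask. With the default configuration
#' the result has exactly 1277 rows: 143 for the original image (24 first
#' order + 17 shape + 26 GLCM + 16 GLRLM + 22 NGTDM/NGLDM + 16 GLSZM +
#' 22 IVH) and 126 for each of the 9 filtered images (shape excluded).
#'
#' @param vol An `image_volume`.
#' @param mask A `binary_mask` sharing `vol`'s geometry; must remain
#'   non-empty after resampling.
#' @param config An [extraction_config()].
#' @param id Optional label used in error messages (e.g. "patient 3 /
#'   observer RA1").
#' @return A tibble with columns `feature_id`, `filter`, `feature_class`,
#'   `name`, `value`.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_patients = 1)
#' ph <- generate_phantom(cfg, patient_seed = 1)
#' feats <- extract_panel(ph$image, ph$truth)
#' nrow(feats)  # 1277
#' }
#' @export
extract_panel <- function(vol, mask, config = extraction_config(), id = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "binary_mask"))
  stopifnot_same_geometry(vol, mask, "image and mask")
  rvol <- resample_isotropic(vol, config$target_spacing)
  rmask <- resample_isotropic(mask, config$target_spacing)
  if (!sum(rmask$indicator))
    stop(sprintf("mask%s is empty after resampling to %g mm",
                 if (is.null(id)) "" else paste0(" (", id, ")"),
                 config$target_spacing), call. = FALSE)
  stack <- filter_stack(rvol, config)
  extract_from_stack(stack, rmask, config)
}

#' Extract the feature panel for every (patient, observer) mask of a cohort
#'
#' The resampled, filtered image stack is computed once per patient and
#' reused across that patient's observers.
#'
#' @param cohort A `study_cohort` (see [generate_cohort()]) or the cohort
#'   built by [run_on_external()].
#' @param config An [extraction_config()].
#' @return Long tibble: `patient_id`, `observer_id`, `discipline`, plus the
#'   [extract_panel()] columns.
#' @export
extract_cohort_features <- function(cohort, config = extraction_config()) {
  stopifnot(inherits(cohort, "study_cohort"))
  disc <- stats::setNames(cohort$observers$discipline, cohort$observers$observer_id)
  out <- purrr::map(cohort$patients, function(p) {
    rvol <- resample_isotropic(p$image, config$target_spacing)
    stack <- filter_stack(rvol, config)
    purrr::imap(p$masks, function(m, obs) {
      rmask <- resample_isotropic(m, config$target_spacing)
      if (!sum(rmask$indicator))
        stop(sprintf("mask of patient %s / observer %s is empty after resampling",
                     p$patient_id, obs), call. = FALSE)
      ft <- extract_from_stack(stack, rmask, config)
      dplyr::mutate(ft, patient_id = p$patient_id, observer_id = obs,
                    discipline = unname(disc[obs]), .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out
}

#' Pivot a long feature table to a wide masks-by-features matrix
#'
#' @param features Long tibble from [extract_cohort_features()].
#' @return Wide tibble, one row per (patient, observer).
#' @export
features_wide <- function(features) {
  tidyr::pivot_wider(features,
                     id_cols = c("patient_id", "observer_id", "discipline"),
                     names_from = "feature_id", values_from = "value")
}
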
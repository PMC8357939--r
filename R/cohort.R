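#' Observer profile
#'
#' Describes one simulated observer: a discipline label and the two knobs of
#' the contouring-error model. Discipline "A" plays the role of a radiation-
#' oncology-like group and "B" a radiology-like group; with the package
#' defaults B contours more conservatively (smaller `volume_bias`) and with
#' larger spread (larger `boundary_noise_sd`) than A, matching the direction
#' of the interdisciplinary effects the pipeline is built to detect.
#'
#' @param observer_id Label.
#' @param discipline `"A"` or `"B"`.
#' @param volume_bias Multiplicative factor on the delineated volume (> 0).
#' @param boundary_noise_sd Radial boundary perturbation SD in mm (>= 0).
#' @param volume_jitter_sd Log-SD of the per-delineation lognormal volume
#'   jitter (mean 1).
#' @return One-row tibble.
#' @export
observer_profile <- function(observer_id, discipline = c("A", "B"),
                             volume_bias = 1, boundary_noise_sd = 0,
                             volume_jitter_sd = 0) {
  discipline <- match.arg(discipline)
  if (volume_bias <= 0) stop("`volume_bias` must be > 0", call. = FALSE)
  if (boundary_noise_sd < 0) stop("`boundary_noise_sd` must be >= 0", call. = FALSE)
  tibble::tibble(observer_id = as.character(observer_id),
                 discipline = discipline,
                 volume_bias = volume_bias,
                 boundary_noise_sd = boundary_noise_sd,
                 volume_jitter_sd = volume_jitter_sd)
}

#' Default six-observer, two-discipline panel
#'
#' Three observers per discipline. Discipline B is configured to contour
#' about two thirds of the true volume (the ratio of the groups' mean
#' volumes reported for radiology vs radiation oncology delineations) and
#' with 2-3x the boundary noise and volume jitter of discipline A.
#'
#' @return Tibble of six [observer_profile()] rows.
#' @export
default_observer_profiles <- function() {
  dplyr::bind_rows(
    observer_profile("RO1", "A", volume_bias = 0.98, boundary_noise_sd = 3.0,
                     volume_jitter_sd = 0.05),
    observer_profile("RO2", "A", volume_bias = 1.00, boundary_noise_sd = 3.5,
                     volume_jitter_sd = 0.05),
    observer_profile("RO3", "A", volume_bias = 1.02, boundary_noise_sd = 4.0,
                     volume_jitter_sd = 0.05),
    observer_profile("RA1", "B", volume_bias = 0.60, boundary_noise_sd = 5.0,
                     volume_jitter_sd = 0.12),
    observer_profile("RA2", "B", volume_bias = 0.66, boundary_noise_sd = 6.0,
                     volume_jitter_sd = 0.12),
    observer_profile("RA3", "B", volume_bias = 0.72, boundary_noise_sd = 7.0,
                     volume_jitter_sd = 0.12))
}

#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic cohort: 21 patients, 6 observers in 2
#' disciplines, low-contrast tumors with mean volume 50 cm^3 (SD 15) on a
#' 5 mm slice / 0.9 mm in-plane grid.
#'
#' @param n_patients Number of patients (>= 1).
#' @param observers Tibble of [observer_profile()] rows (>= 2 observers).
#' @param tumor_volume_mean,tumor_volume_sd Tumor volume distribution, cm^3.
#' @param tumor_contrast Tumor-vs-background intensity offset (CT-number-like
#'   units).
#' @param image_noise_sd White intensity noise SD.
#' @param texture_sd SD of the spatially correlated background texture.
#' @param texture_corr_mm Correlation length of the background texture, mm.
#' @param gradient_amp Peak-to-center amplitude of the linear background
#'   intensity gradient.
#' @param background_level Baseline background intensity.
#' @param blob_perturb_amp Relative amplitude of the random blob shape
#'   perturbation.
#' @param noise_corr_mm Surface correlation length of observer boundary
#'   noise, mm.
#' @param native_spacing Native voxel spacing in mm (x, y, z).
#' @param fov_mm Field of view in mm per axis.
#' @param master_seed Integer master seed; the cohort is a pure function of
#'   (config, master_seed).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 21,
                          observers = default_observer_profiles(),
                          tumor_volume_mean = 50, tumor_volume_sd = 15,
                          tumor_contrast = 40,
                          image_noise_sd = 15, texture_sd = 10,
                          texture_corr_mm = 4, gradient_amp = 10,
                          background_level = 40, blob_perturb_amp = 0.10,
                          noise_corr_mm = 10,
                          native_spacing = c(0.9, 0.9, 5),
                          fov_mm = c(96, 96, 100),
                          master_seed = 1L) {
  if (n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  if (!is.data.frame(observers) || nrow(observers) < 2)
    stop("need at least 2 observers", call. = FALSE)
  if (anyDuplicated(observers$observer_id))
    stop("observer ids must be unique", call. = FALSE)
  if (any(native_spacing <= 0) || length(native_spacing) != 3)
    stop("`native_spacing` must be 3 positive numbers", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), observers = observers,
                 tumor_volume_mean = tumor_volume_mean,
                 tumor_volume_sd = tumor_volume_sd,
                 tumor_contrast = tumor_contrast,
                 image_noise_sd = image_noise_sd, texture_sd = texture_sd,
                 texture_corr_mm = texture_corr_mm,
                 gradient_amp = gradient_amp,
                 background_level = background_level,
                 blob_perturb_amp = blob_perturb_amp,
                 noise_corr_mm = noise_corr_mm,
                 native_spacing = as.numeric(native_spacing),
                 fov_mm = as.numeric(fov_mm),
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Counter-based per-patient / per-observer seed derivation
#'
#' `seed = (master + 104729 * patient_index + 7919 * observer_index) mod
#' (2^31 - 1)`, with `observer_index = 0` for the patient-level phantom
#' draw. Adding patients or observers never reshuffles the seeds of
#' existing ones.
#'
#' @param master_seed Integer master seed.
#' @param patient_index 1-based patient counter.
#' @param observer_index 1-based observer counter, or 0 for the phantom.
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, patient_index, observer_index = 0L) {
  as.integer((as.double(master_seed) + 104729 * patient_index +
                7919 * observer_index) %% (2^31 - 1))
}

#' Generate a synthetic multi-observer study cohort
#'
#' Deterministic function of `(config, config$master_seed)`: for each
#' patient a phantom image and ground-truth mask are generated
#' ([generate_phantom()]), then each observer's delineation is simulated
#' ([simulate_observer_mask()]) with its own derived seed.
#'
#' @param config A [cohort_config()].
#' @return A `study_cohort`: list with `patients` (each holding
#'   `patient_id`, `image`, `truth`, and a named list `masks`), `observers`,
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  obs <- config$observers
  patients <- purrr::map(seq_len(config$n_patients), function(i) {
    ph <- generate_phantom(config, derive_seed(config$master_seed, i, 0L))
    sdist <- signed_distance(ph$truth)
    masks <- purrr::map(seq_len(nrow(obs)), function(j) {
      simulate_observer_mask(ph$truth, obs[j, ],
                             seed = derive_seed(config$master_seed, i, j),
                             noise_corr_mm = config$noise_corr_mm,
                             sdist = sdist)
    })
    names(masks) <- obs$observer_id
    list(patient_id = sprintf("P%02d", i), image = ph$image,
         truth = ph$truth, masks = masks)
  })
  structure(list(patients = patients, observers = obs, config = config),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort> %d patients x %d observers (%s)\n",
              length(x$patients), nrow(x$observers),
              paste(sprintf("%s: %d", unique(x$observers$discipline),
                            table(x$observers$discipline)[unique(x$observers$discipline)]),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk as NIfTI files plus a manifest
#'
#' Layout: `images/<patient>.nii`, `truth/<patient>.nii`,
#' `masks/<patient>_<observer>.nii`, and `manifest.tsv` with columns
#' `patient_id`, `observer_id`, `discipline`, `image_path`, `mask_path`
#' (one row per observer mask; paths relative to `dir`).
#'
#' @param cohort A `study_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "study_cohort"))
  for (sub in c("images", "truth", "masks"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  disc <- stats::setNames(cohort$observers$discipline,
                          cohort$observers$observer_id)
  rows <- purrr::map(cohort$patients, function(p) {
    img_rel <- file.path("images", paste0(p$patient_id, ".nii"))
    write_volume(p$image, file.path(dir, img_rel))
    if (!is.null(p$truth))
      write_mask(p$truth, file.path(dir, "truth", paste0(p$patient_id, ".nii")))
    purrr::imap(p$masks, function(m, obs) {
      rel <- file.path("masks", paste0(p$patient_id, "_", obs, ".nii"))
      write_mask(m, file.path(dir, rel))
      tibble::tibble(patient_id = p$patient_id, observer_id = obs,
                     discipline = unname(disc[obs]),
                     image_path = img_rel, mask_path = rel)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  readr::write_tsv(rows, file.path(dir, "manifest.tsv"))
  invisible(rows)
}

#' Load a cohort from a manifest of NIfTI images and masks
#'
#' Validates the manifest (required columns, files present, consistent
#' geometry per patient, at least two observers per patient) before reading
#' everything into a `study_cohort`. All validation failures are reported
#' together.
#'
#' @param manifest Path to a delimited manifest file, or a data frame with
#'   columns `patient_id`, `observer_id`, `discipline`, `image_path`,
#'   `mask_path`.
#' @param base_dir Directory that relative paths are resolved against;
#'   defaults to the manifest's directory.
#' @return A `study_cohort` (with `truth = NULL` for each patient).
#' @export
load_cohort <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  need <- c("patient_id", "observer_id", "discipline", "image_path", "mask_path")
  missing_cols <- setdiff(need, names(manifest))
  problems <- character()
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  manifest <- dplyr::as_tibble(manifest)
  obs_per_patient <- dplyr::count(manifest, .data$patient_id)
  bad <- obs_per_patient$patient_id[obs_per_patient$n < 2]
  if (length(bad))
    problems <- c(problems, sprintf("patient %s has fewer than 2 observer masks",
                                    bad))
  by_obs <- dplyr::distinct(manifest, .data$observer_id, .data$discipline)
  if (anyDuplicated(by_obs$observer_id))
    problems <- c(problems, "an observer id is mapped to two disciplines")
  all_obs <- unique(manifest$observer_id)
  for (pid in unique(manifest$patient_id)) {
    gap <- setdiff(all_obs, manifest$observer_id[manifest$patient_id == pid])
    if (length(gap))
      problems <- c(problems,
                    sprintf("patient %s lacks a mask from observer %s",
                            pid, gap))
  }
  paths <- unique(c(file.path(base_dir, manifest$image_path),
                    file.path(base_dir, manifest$mask_path)))
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    problems <- c(problems, sprintf("missing file: %s", absent))
  if (length(problems))
    stop("cohort manifest validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  obs <- dplyr::arrange(by_obs, .data$observer_id)
  patients <- manifest |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      img <- read_volume(file.path(base_dir, g$image_path[1]))
      masks <- purrr::map(seq_len(nrow(g)), function(r) {
        m <- read_mask(file.path(base_dir, g$mask_path[r]))
        if (!same_geometry(img, m))
          stop(sprintf("patient %s / observer %s: mask geometry does not match the image",
                       g$patient_id[1], g$observer_id[r]), call. = FALSE)
        m
      })
      names(masks) <- g$observer_id
      list(patient_id = g$patient_id[1], image = img, truth = NULL,
           masks = masks)
    })
  structure(list(patients = patients, observers = obs,
                 config = NULL, manifest = manifest),
            class = "study_cohort")
}
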
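#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`, the standard overlap measure:
#' 1 for identical masks, 0 for disjoint ones. Symmetric in its arguments.
#' When both masks are empty the coefficient is defined as 1 (documented
#' convention; two empty delineations agree perfectly).
#'
#' @param a,b `binary_mask`s sharing one grid geometry.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stopifnot_same_geometry(a, b, "masks")
  na <- sum(a$indicator)
  nb <- sum(b$indicator)
  if (na + nb == 0) return(1)
  2 * sum(a$indicator & b$indicator) / (na + nb)
}

#' Grade a DSC value on the four-level agreement scale
#'
#' `DSC >= 0.85` is High, `0.85 > DSC >= 0.70` Medium, `0.70 > DSC >= 0.5`
#' Low, and `DSC < 0.5` Very Low agreement. Boundaries are inclusive from
#' above exactly as on that scale.
#'
#' @param dsc Numeric vector of DSC values in `[0, 1]`.
#' @return Factor with levels `High`, `Medium`, `Low`, `VeryLow`.
#' @export
grade_agreement <- function(dsc) {
  if (any(!is.finite(dsc)) || any(dsc < 0 | dsc > 1))
    stop("`dsc` must be within [0, 1]", call. = FALSE)
  g <- ifelse(dsc >= 0.85, "High",
              ifelse(dsc >= 0.70, "Medium",
                     ifelse(dsc >= 0.5, "Low", "VeryLow")))
  factor(g, levels = c("High", "Medium", "Low", "VeryLow"))
}

#' Per-patient consensus building and observer agreement
#'
#' For each patient, a consensus mask is built with [staple()] over all of
#' that patient's observers jointly, and each observer's delineation is
#' scored against it with [dice()]. DSC and STAPLE are computed on the
#' native (pre-resampling) mask grid, where the contours were drawn;
#' isotropic resampling is a feature-extraction concern only.
#'
#' @param cohort A `study_cohort`.
#' @param tol,max_iter Passed to [staple()].
#' @return A tibble of class `seg_agreement` with one row per
#'   (patient, observer): `patient_id`, `observer_id`, `discipline`,
#'   `volume_cm3`, `dsc`, `grade`. The per-patient STAPLE fits are attached
#'   as the `staple` attribute (a named list).
#' @export
per_patient_agreement <- function(cohort, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(cohort, "study_cohort"))
  disc <- stats::setNames(cohort$observers$discipline,
                          cohort$observers$observer_id)
  fits <- list()
  rows <- purrr::map(cohort$patients, function(p) {
    fit <- staple(p$masks, tol = tol, max_iter = max_iter)
    fits[[p$patient_id]] <<- fit
    dscs <- vapply(p$masks, function(m) dice(m, fit$consensus), numeric(1))
    tibble::tibble(patient_id = p$patient_id,
                   observer_id = names(p$masks),
                   discipline = unname(disc[names(p$masks)]),
                   volume_cm3 = vapply(p$masks, mask_volume_cm3, numeric(1)),
                   dsc = unname(dscs),
                   grade = grade_agreement(unname(dscs)))
  }) |> dplyr::bind_rows()
  structure(rows, class = c("seg_agreement", class(rows)), staple = fits)
}

#' Per-patient, per-discipline DSC summaries
#'
#' @param records A `seg_agreement` tibble from [per_patient_agreement()].
#' @return Tibble with `patient_id`, `discipline`, `mean_dsc`, `sd_dsc`,
#'   `mean_volume_cm3`, `sd_volume_cm3`.
#' @export
agreement_summary <- function(records) {
  records |>
    dplyr::group_by(.data$patient_id, .data$discipline) |>
    dplyr::summarise(mean_dsc = mean(.data$dsc),
                     sd_dsc = stats::sd(.data$dsc),
                     mean_volume_cm3 = mean(.data$volume_cm3),
                     sd_volume_cm3 = stats::sd(.data$volume_cm3),
                     .groups = "drop")
}

# Paired two-tailed t-test on per-patient discipline means of `var`.
# Degenerate zero-variance differences are handled explicitly: p = 0 when
# the mean difference is nonzero (the paired t statistic diverges), p = 1
# when all differences are zero.
paired_discipline_test <- function(records, var) {
  wide <- records |>
    dplyr::group_by(.data$patient_id, .data$discipline) |>
    dplyr::summarise(m = mean(.data[[var]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "discipline", values_from = "m")
  if (!all(c("A", "B") %in% names(wide)) || anyNA(wide$A) || anyNA(wide$B))
    stop("both disciplines must be present for every patient", call. = FALSE)
  if (nrow(wide) < 2) stop("need at least 2 patients", call. = FALSE)
  d <- wide$A - wide$B
  if (stats::sd(d) < 1e-12 * max(1, abs(mean(d)))) {
    if (mean(d) == 0)
      return(tibble::tibble(n_patients = length(d), mean_diff = 0,
                            statistic = 0, df = length(d) - 1, p_value = 1,
                            degenerate = TRUE))
    return(tibble::tibble(n_patients = length(d), mean_diff = mean(d),
                          statistic = sign(mean(d)) * Inf, df = length(d) - 1,
                          p_value = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(wide$A, wide$B, paired = TRUE)
  tibble::tibble(n_patients = length(d), mean_diff = mean(d),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, degenerate = FALSE)
}

#' Paired discipline comparison of consensus agreement
#'
#' Per-patient discipline-mean DSC values, paired by patient, compared with
#' a paired two-tailed t-test.
#'
#' @param records A `seg_agreement` tibble; both disciplines must be present
#'   for every patient.
#' @return One-row tibble: `n_patients`, `mean_diff` (A - B), `statistic`,
#'   `df`, `p_value`, `degenerate`.
#' @export
compare_disciplines_dsc <- function(records) {
  paired_discipline_test(records, "dsc")
}

#' Discipline volume comparison
#'
#' Per-discipline mean and SD of delineated volume (cm^3; voxel count times
#' voxel volume on the native grid) plus a paired two-tailed t-test of the
#' per-patient discipline means.
#'
#' @param x A `study_cohort` or a `seg_agreement` tibble.
#' @return One-row tibble: `mean_volume_A`, `sd_volume_A`, `mean_volume_B`,
#'   `sd_volume_B` (cm^3), and the [compare_disciplines_dsc()]-style test
#'   columns.
#' @export
compare_volumes <- function(x) {
  records <- if (inherits(x, "study_cohort")) cohort_volumes(x) else x
  test <- paired_discipline_test(records, "volume_cm3")
  summ <- records |>
    dplyr::group_by(.data$discipline) |>
    dplyr::summarise(mean = mean(.data$volume_cm3),
                     sd = stats::sd(.data$volume_cm3), .groups = "drop")
  tibble::tibble(
    mean_volume_A = summ$mean[summ$discipline == "A"],
    sd_volume_A = summ$sd[summ$discipline == "A"],
    mean_volume_B = summ$mean[summ$discipline == "B"],
    sd_volume_B = summ$sd[summ$discipline == "B"],
    statistic = test$statistic, df = test$df, p_value = test$p_value)
}

cohort_volumes <- function(cohort) {
  disc <- stats::setNames(cohort$observers$discipline,
                          cohort$observers$observer_id)
  purrr::map(cohort$patients, function(p)
    tibble::tibble(patient_id = p$patient_id,
                   observer_id = names(p$masks),
                   discipline = unname(disc[names(p$masks)]),
                   volume_cm3 = vapply(p$masks, mask_volume_cm3, numeric(1)))) |>
    dplyr::bind_rows()
}
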
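# ggplot2 views of the result tables.

#' Plot per-patient observer agreement
#'
#' Mean DSC per patient and discipline with +/- 1 SD bars, over shaded bands
#' for the four agreement grades.
#'
#' @param object A `seg_agreement` tibble from [per_patient_agreement()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seg_agreement <- function(object, ...) {
  summ <- agreement_summary(object)
  bands <- tibble::tibble(lo = c(0.85, 0.70, 0.50, 0.00),
                          hi = c(1.00, 0.85, 0.70, 0.50),
                          grade = factor(c("High", "Medium", "Low", "VeryLow"),
                                         levels = c("High", "Medium", "Low",
                                                    "VeryLow")))
  ggplot2::ggplot(summ) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lo,
                                    ymax = .data$hi, fill = .data$grade),
                       alpha = 0.15) +
    ggplot2::geom_pointrange(
      ggplot2::aes(x = .data$patient_id, y = .data$mean_dsc,
                   ymin = pmax(0, .data$mean_dsc - .data$sd_dsc),
                   ymax = pmin(1, .data$mean_dsc + .data$sd_dsc),
                   color = .data$discipline),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_fill_manual(values = c(High = "#1b9e77", Medium = "#7570b3",
                                          Low = "#d95f02", VeryLow = "#e7298a"),
                               name = "agreement") +
    ggplot2::labs(x = "patient", y = "DSC vs consensus", color = "discipline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot ICC distributions per image filter and group
#'
#' @param object An `icc_records` tibble from [feature_icc_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icc_records <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- dplyr::filter(object, !is.na(.data$icc), .data$group %in% c("A", "B"))
  df$filter <- factor(df$filter, levels = unique(object$filter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$filter, y = .data$icc,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(x = "image filter", y = "ICC(2,1)", fill = "discipline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Rank-vs-rank robustness agreement plot
#'
#' Scatter of discipline-B robustness ranks against discipline-A ranks per
#' feature class, with the least-squares line. Perfect agreement lies on the
#' 45-degree diagonal.
#'
#' @param records An `icc_records` tibble (usually restricted to the
#'   original-image features).
#' @return A ggplot object.
#' @export
plot_rank_agreement <- function(records) {
  wide <- records |>
    dplyr::filter(.data$group %in% c("A", "B")) |>
    dplyr::select("feature_id", "feature_class", "group", "icc") |>
    tidyr::pivot_wider(names_from = "group", values_from = "icc") |>
    dplyr::filter(!is.na(.data$A), !is.na(.data$B)) |>
    dplyr::group_by(.data$feature_class) |>
    dplyr::mutate(rank_A = rank(.data$A), rank_B = rank(.data$B)) |>
    dplyr::ungroup()
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$rank_A, y = .data$rank_B)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey70") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "#d95f02") +
    ggplot2::facet_wrap(~feature_class, scales = "free") +
    ggplot2::labs(x = "robustness rank (discipline A)",
                  y = "robustness rank (discipline B)") +
    ggplot2::theme_minimal()
}
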
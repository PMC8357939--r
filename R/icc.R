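#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measurement, absolute-agreement
#' intraclass correlation of an n subjects x k raters matrix:
#' `ICC(2,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`
#' where `MS_R`, `MS_C`, `MS_E` are the between-subject, between-rater and
#' residual mean squares of the two-way ANOVA decomposition. Mean squares
#' are computed from explicit sums of squares, not via a linear-model fit.
#' The value can be negative and is reported as computed. When the
#' denominator is (numerically) zero -- e.g. a matrix with no variance at
#' all -- the value is `NA` with `flagged = TRUE`.
#'
#' @param m Numeric matrix, n >= 2 subjects (rows) x k >= 2 raters
#'   (columns), no missing cells.
#' @return An `icc21` object: list with `icc`, `ms_subject`, `ms_rater`,
#'   `ms_error`, `n`, `k`, `flagged`.
#' @examples
#' m <- cbind(c(1, 3, 5), c(2, 4, 6))
#' icc21(m)$icc
#' @export
icc21 <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) < 2 || ncol(m) < 2)
    stop("`m` must be a numeric matrix with >= 2 rows and >= 2 columns",
         call. = FALSE)
  if (any(!is.finite(m)))
    stop("rating matrix contains non-finite cells", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  g <- mean(m)
  ssr <- k * sum((rowMeans(m) - g)^2)
  ssc <- n * sum((colMeans(m) - g)^2)
  sst <- sum((m - g)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  scale <- max(msr, msc, mse)
  flagged <- scale == 0 || abs(den) < 1e-12 * scale
  icc <- if (flagged) NA_real_ else (msr - mse) / den
  structure(list(icc = icc, ms_subject = msr, ms_rater = msc, ms_error = mse,
                 n = n, k = k, flagged = flagged),
            class = "icc21")
}

#' @export
print.icc21 <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %s  [n = %d subjects, k = %d raters]\n",
              if (x$flagged) "NA (degenerate)" else format(x$icc, digits = 6),
              x$n, x$k))
  cat(sprintf("  MS subject %.6g, MS rater %.6g, MS error %.6g\n",
              x$ms_subject, x$ms_rater, x$ms_error))
  invisible(x)
}

#' @export
tidy.icc21 <- function(x, ...) {
  tibble::tibble(term = c("subject", "rater", "error"),
                 mean_square = c(x$ms_subject, x$ms_rater, x$ms_error))
}

#' @export
glance.icc21 <- function(x, ...) {
  tibble::tibble(icc = x$icc, n = x$n, k = x$k, flagged = x$flagged)
}

# Vectorized ICC(2,1) over an n x k x F array; returns icc (NA when
# flagged). A feature with zero between-subject variance is flagged as
# degenerate.
icc21_bulk <- function(A) {
  dd <- dim(A)
  n <- dd[1]; k <- dd[2]; F <- dd[3]
  g <- colMeans(matrix(A, n * k, F))
  rm <- colMeans(aperm(A, c(2, 1, 3)))        # n x F subject means
  cm <- colMeans(A)                           # k x F rater means
  ssr <- k * colSums((rm - rep(g, each = n))^2)
  ssc <- n * colSums((cm - rep(g, each = k))^2)
  sst <- colSums((matrix(A, n * k, F) - rep(g, each = n * k))^2)
  sse <- pmax(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  scale <- pmax(msr, msc, mse)
  flagged <- scale == 0 | abs(den) < 1e-12 * scale | msr <= 1e-12 * scale
  icc <- ifelse(flagged, NA_real_, (msr - mse) / den)
  icc
}

#' Per-feature ICC(2,1) table by observer group
#'
#' Assembles, for every feature, a patients x raters rating matrix for each
#' requested observer group (all observers jointly and each discipline
#' separately by default) and computes ICC(2,1). A feature with zero
#' variance across subjects in a group, or a degenerate denominator, gets a
#' flagged `NA` ICC, which is never robust and is excluded from downstream
#' paired tests and rank regressions.
#'
#' @param features Long feature tibble from [extract_cohort_features()].
#' @param groups Named list mapping group label to observer ids; default
#'   `all` plus one group per discipline.
#' @param threshold Robustness threshold: a feature is robust when
#'   `icc > threshold` (strict inequality; default 0.75).
#' @return Tibble of class `icc_records`: `feature_id`, `filter`,
#'   `feature_class`, `name`, `group`, `icc`, `robust`.
#' @export
feature_icc_table <- function(features, groups = NULL, threshold = 0.75) {
  need <- c("patient_id", "observer_id", "discipline", "feature_id",
            "filter", "feature_class", "name", "value")
  if (!all(need %in% names(features)))
    stop("`features` lacks columns: ",
         paste(setdiff(need, names(features)), collapse = ", "), call. = FALSE)
  if (anyNA(features$value) || any(!is.finite(features$value)))
    stop("feature table contains non-finite values", call. = FALSE)
  obs <- dplyr::distinct(features, .data$observer_id, .data$discipline)
  if (is.null(groups)) {
    # per-discipline groups require >= 2 raters; a singleton discipline is
    # skipped rather than failing the whole table
    disc <- split(obs$observer_id, obs$discipline)
    groups <- c(list(all = obs$observer_id), disc[lengths(disc) >= 2])
  }
  meta <- dplyr::distinct(features, .data$feature_id, .data$filter,
                          .data$feature_class, .data$name)
  patients <- sort(unique(features$patient_id))
  fids <- meta$feature_id
  out <- purrr::imap(groups, function(obs_ids, lab) {
    if (length(obs_ids) < 2)
      stop(sprintf("group %s has fewer than 2 observers", lab), call. = FALSE)
    sub <- dplyr::filter(features, .data$observer_id %in% obs_ids)
    n_expected <- length(patients) * length(obs_ids) * length(fids)
    if (nrow(sub) != n_expected)
      stop(sprintf("group %s: missing feature vectors (%d rows, expected %d)",
                   lab, nrow(sub), n_expected), call. = FALSE)
    sub <- dplyr::arrange(sub,
                          match(.data$feature_id, fids),
                          match(.data$observer_id, obs_ids),
                          match(.data$patient_id, patients))
    A <- array(sub$value, c(length(patients), length(obs_ids), length(fids)))
    icc <- icc21_bulk(A)
    dplyr::mutate(meta, group = lab, icc = icc,
                  robust = !is.na(icc) & icc > threshold)
  }) |> dplyr::bind_rows()
  structure(out, class = c("icc_records", class(out)), threshold = threshold)
}

#' Robust-feature summary per filter, feature class and group
#'
#' @param records An `icc_records` tibble.
#' @return Tibble with `group`, `filter`, `feature_class`, `total`,
#'   `robust`, `pct_robust`.
#' @seealso [robust_intersection()] for the cross-group robust-set overlap.
#' @export
robust_summary <- function(records) {
  records |>
    dplyr::group_by(.data$group, .data$filter, .data$feature_class) |>
    dplyr::summarise(total = dplyr::n(), robust = sum(.data$robust),
                     pct_robust = 100 * mean(.data$robust), .groups = "drop")
}

#' Size of the robust-feature set shared by two groups
#'
#' @param records An `icc_records` tibble.
#' @param groups Length-2 character vector of group labels.
#' @return Integer count of features robust in both groups.
#' @export
robust_intersection <- function(records, groups = c("A", "B")) {
  sets <- lapply(groups, function(g)
    records$feature_id[records$group == g & records$robust])
  length(intersect(sets[[1]], sets[[2]]))
}

#' Top-ranked features per filter by ICC
#'
#' @param records An `icc_records` tibble.
#' @param group Group label to rank within.
#' @param per_filter_k Number of features per filter (ties broken by ICC
#'   descending, then feature name ascending; flagged ICCs rank last).
#' @return Tibble with `filter`, `rank`, `feature_id`, `icc`.
#' @export
top_features <- function(records, group = "all", per_filter_k = 3L) {
  records |>
    dplyr::filter(.data$group == !!group, !is.na(.data$icc)) |>
    dplyr::arrange(.data$filter, dplyr::desc(.data$icc), .data$feature_id) |>
    dplyr::group_by(.data$filter) |>
    dplyr::slice_head(n = per_filter_k) |>
    dplyr::mutate(rank = dplyr::row_number(), .after = "filter") |>
    dplyr::ungroup() |>
    dplyr::select("filter", "rank", "feature_id", "icc")
}

#' Per-filter Wilcoxon signed-rank comparison of discipline ICCs
#'
#' Within each image filter, the per-feature (ICC_A, ICC_B) pairs are
#' compared with a two-sided Wilcoxon signed-rank test. Features flagged in
#' either group are dropped; zero differences are dropped by the standard
#' signed-rank convention; the exact null distribution is used for small
#' samples without ties and the normal approximation otherwise.
#'
#' @param records An `icc_records` tibble containing groups `A` and `B`.
#' @return Tibble: `filter`, `n_pairs`, `statistic`, `p_value`,
#'   `degenerate` (all differences zero).
#' @export
discipline_icc_wilcoxon <- function(records) {
  wide <- records |>
    dplyr::filter(.data$group %in% c("A", "B")) |>
    dplyr::select("feature_id", "filter", "group", "icc") |>
    tidyr::pivot_wider(names_from = "group", values_from = "icc") |>
    dplyr::filter(!is.na(.data$A), !is.na(.data$B))
  wide |>
    dplyr::group_by(.data$filter) |>
    dplyr::group_modify(function(g, key) {
      d <- g$A - g$B
      if (all(d == 0))
        return(tibble::tibble(n_pairs = nrow(g), statistic = NA_real_,
                              p_value = NA_real_, degenerate = TRUE))
      wt <- suppressWarnings(stats::wilcox.test(g$A, g$B, paired = TRUE))
      tibble::tibble(n_pairs = sum(d != 0), statistic = unname(wt$statistic),
                     p_value = wt$p.value, degenerate = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Rank agreement of feature robustness between disciplines
#'
#' Within each feature class, features are ranked by ICC separately for
#' groups A and B (ties get average ranks; flagged features are dropped
#' pairwise), and the B ranks are regressed on the A ranks by ordinary least
#' squares. Identical rankings give slope 1 and R^2 = 1; exactly reversed
#' rankings give slope -1 and R^2 = 1.
#'
#' @param records An `icc_records` tibble (typically filtered to the
#'   original-image features).
#' @return Tibble: `feature_class`, `n`, `slope`, `r_squared`.
#' @export
rank_agreement <- function(records) {
  wide <- records |>
    dplyr::filter(.data$group %in% c("A", "B")) |>
    dplyr::select("feature_id", "feature_class", "group", "icc") |>
    tidyr::pivot_wider(names_from = "group", values_from = "icc") |>
    dplyr::filter(!is.na(.data$A), !is.na(.data$B))
  wide |>
    dplyr::group_by(.data$feature_class) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 3)
        stop(sprintf("feature class %s has fewer than 3 rankable features",
                     key$feature_class), call. = FALSE)
      ra <- rank(g$A)
      rb <- rank(g$B)
      fit <- stats::lm(rb ~ ra)
      tibble::tibble(n = nrow(g),
                     slope = unname(stats::coef(fit)[2]),
                     r_squared = summary(fit)$r.squared)
    }) |>
    dplyr::ungroup()
}
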
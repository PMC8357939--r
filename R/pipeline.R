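#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end study: cohort simulation,
#' feature extraction, STAPLE convergence, and the robustness threshold.
#'
#' @param cohort A [cohort_config()].
#' @param extraction An [extraction_config()].
#' @param staple_tol,staple_max_iter STAPLE convergence controls.
#' @param icc_threshold Robustness threshold on ICC(2,1).
#' @param top_k Features per filter in the top-feature table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            extraction = extraction_config(),
                            staple_tol = 1e-6, staple_max_iter = 100L,
                            icc_threshold = 0.75, top_k = 3L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(extraction, "extraction_config"))
  structure(list(cohort = cohort, extraction = extraction,
                 staple_tol = staple_tol,
                 staple_max_iter = as.integer(staple_max_iter),
                 icc_threshold = icc_threshold, top_k = as.integer(top_k)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass_deep(config), file = tmp,
       control = c("keepNA", "keepInteger", "digits17"))
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[segrobust %s] %s",
                              format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

# A stage is up to date when its stamp file holds the current input hash and
# all its outputs exist.
stage_current <- function(out_dir, stage, hash, outputs) {
  stamp <- file.path(out_dir, "stamps", paste0(stage, ".hash"))
  file.exists(stamp) &&
    identical(readLines(stamp, warn = FALSE)[1], hash) &&
    all(file.exists(file.path(out_dir, outputs)))
}

stage_stamp <- function(out_dir, stage, hash) {
  dir.create(file.path(out_dir, "stamps"), recursive = TRUE, showWarnings = FALSE)
  writeLines(hash, file.path(out_dir, "stamps", paste0(stage, ".hash")))
}

#' Run the full study pipeline
#'
#' Orchestrates simulate -> consensus -> extract -> robustness from one
#' configuration. Every stage persists its artifacts under `out_dir`
#' (NIfTI volumes, flat TSV tables, a JSON run manifest); with
#' `resume = TRUE` a stage whose inputs are unchanged (content-hash check)
#' is reloaded from disk instead of recomputed. The run is a deterministic
#' function of `(config, config$cohort$master_seed)`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if missing.
#' @param resume Reuse persisted stages whose inputs are unchanged.
#' @param quiet Suppress per-stage log messages.
#' @return A `segrobust_report`: list with the agreement table, volume
#'   comparison, DSC discipline test, feature table, ICC records, robust
#'   summary, robust intersection, top features, per-filter Wilcoxon
#'   p-values, rank-agreement table, and the run manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, resume = TRUE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  # -- simulate ---------------------------------------------------------
  hash_sim <- config_fingerprint(config$cohort)
  if (resume && stage_current(out_dir, "simulate", hash_sim,
                              file.path("cohort", "manifest.tsv"))) {
    stage_log(quiet, "simulate: reusing persisted cohort")
    cohort <- load_cohort(file.path(out_dir, "cohort", "manifest.tsv"))
  } else {
    stage_log(quiet, "simulate: generating %d patients x %d observers (seed %d)",
              config$cohort$n_patients, nrow(config$cohort$observers),
              config$cohort$master_seed)
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    stage_stamp(out_dir, "simulate", hash_sim)
  }

  # -- consensus + agreement -------------------------------------------
  tables <- file.path(out_dir, "tables")
  dir.create(tables, recursive = TRUE, showWarnings = FALSE)
  hash_cons <- paste(hash_sim, config$staple_tol, config$staple_max_iter,
                     sep = "|")
  agree_path <- file.path("tables", "agreement.tsv")
  if (resume && stage_current(out_dir, "consensus", hash_cons, agree_path)) {
    stage_log(quiet, "consensus: reusing persisted agreement table")
    agreement <- readr::read_tsv(file.path(out_dir, agree_path),
                                 show_col_types = FALSE)
    agreement$grade <- factor(agreement$grade,
                              levels = c("High", "Medium", "Low", "VeryLow"))
  } else {
    stage_log(quiet, "consensus: STAPLE + DSC on %d patients",
              length(cohort$patients))
    agreement <- per_patient_agreement(cohort, tol = config$staple_tol,
                                       max_iter = config$staple_max_iter)
    dir.create(file.path(out_dir, "consensus"), showWarnings = FALSE)
    fits <- attr(agreement, "staple")
    for (pid in names(fits))
      write_mask(fits[[pid]]$consensus,
                 file.path(out_dir, "consensus", paste0(pid, ".nii")))
    write_table(agreement, file.path(out_dir, agree_path))
    stage_stamp(out_dir, "consensus", hash_cons)
  }
  volume_cmp <- compare_volumes(cohort)
  dsc_test <- compare_disciplines_dsc(agreement)
  write_table(volume_cmp, file.path(tables, "volume_comparison.tsv"))
  write_table(dsc_test, file.path(tables, "dsc_discipline_test.tsv"))

  # -- extract ----------------------------------------------------------
  hash_ext <- paste(hash_sim, config_fingerprint(config$extraction), sep = "|")
  feat_path <- file.path("tables", "features.tsv")
  if (resume && stage_current(out_dir, "extract", hash_ext, feat_path)) {
    stage_log(quiet, "extract: reusing persisted feature table")
    features <- readr::read_tsv(file.path(out_dir, feat_path),
                                show_col_types = FALSE)
  } else {
    stage_log(quiet, "extract: %d-filter panel on %d masks",
              length(config$extraction$filters),
              sum(lengths(purrr::map(cohort$patients, "masks"))))
    features <- extract_cohort_features(cohort, config$extraction)
    write_table(features, file.path(out_dir, feat_path))
    stage_stamp(out_dir, "extract", hash_ext)
  }

  # -- robustness -------------------------------------------------------
  stage_log(quiet, "robustness: ICC(2,1) per feature and group")
  icc_records <- feature_icc_table(features, threshold = config$icc_threshold)
  summary_tbl <- robust_summary(icc_records)
  cmp <- discipline_tables(icc_records, config$top_k)
  overlap <- cmp$overlap
  top_tbl <- cmp$top
  wilcoxon <- cmp$wilcoxon
  ranks <- cmp$ranks
  write_table(icc_records, file.path(tables, "icc_records.tsv"))
  write_table(summary_tbl, file.path(tables, "robust_summary.tsv"))
  write_table(top_tbl, file.path(tables, "top_features.tsv"))
  write_table(wilcoxon, file.path(tables, "wilcoxon.tsv"))
  write_table(ranks, file.path(tables, "rank_agreement.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("segrobust")),
    master_seed = config$cohort$master_seed,
    config_hash = config_fingerprint(config),
    n_patients = length(cohort$patients),
    n_observers = nrow(cohort$observers),
    n_features = length(unique(features$feature_id)),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log(quiet, "done in %.1f s", manifest$elapsed_sec)

  structure(list(agreement = agreement, volume_comparison = volume_cmp,
                 dsc_test = dsc_test, features = features,
                 icc_records = icc_records, robust_summary = summary_tbl,
                 robust_intersection = overlap, top_features = top_tbl,
                 wilcoxon = wilcoxon, rank_agreement = ranks,
                 manifest = manifest, out_dir = out_dir, config = config),
            class = "segrobust_report")
}

# Discipline-split comparison tables; skipped (empty) when a discipline
# lacks the two observers an ICC group needs.
discipline_tables <- function(icc_records, top_k) {
  grps <- unique(icc_records$group)
  top <- dplyr::bind_rows(
    lapply(stats::setNames(grps, grps), function(g)
      top_features(icc_records, g, top_k)),
    .id = "group")
  if (all(c("A", "B") %in% grps)) {
    list(overlap = robust_intersection(icc_records, c("A", "B")),
         top = top,
         wilcoxon = discipline_icc_wilcoxon(icc_records),
         ranks = rank_agreement(
           dplyr::filter(icc_records, .data$filter == "original")))
  } else {
    list(overlap = NA_integer_, top = top,
         wilcoxon = tibble::tibble(filter = character(), n_pairs = integer(),
                                   statistic = numeric(), p_value = numeric(),
                                   degenerate = logical()),
         ranks = tibble::tibble(feature_class = character(), n = integer(),
                                slope = numeric(), r_squared = numeric()))
  }
}

# Fixed-format TSV writer so identical inputs give byte-identical files.
write_table <- function(x, path) {
  x <- dplyr::mutate(dplyr::as_tibble(x), dplyr::across(
    dplyr::where(is.factor), as.character))
  readr::write_tsv(x, path)
  invisible(path)
}

#' Run the consensus/extraction/robustness stages on user-supplied data
#'
#' Identical downstream behavior to [run_pipeline()], but the cohort comes
#' from a manifest of existing NIfTI images and masks instead of the
#' simulator. The manifest and all geometries are validated before any
#' computation starts.
#'
#' @param manifest Manifest path or data frame (see [load_cohort()]).
#' @param config A [pipeline_config()]; its `cohort` entry is ignored.
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage log messages.
#' @return A `segrobust_report`.
#' @export
run_on_external <- function(manifest, config = pipeline_config(), out_dir,
                            quiet = FALSE) {
  cohort <- load_cohort(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- file.path(out_dir, "tables")
  dir.create(tables, showWarnings = FALSE)
  stage_log(quiet, "consensus: STAPLE + DSC on %d patients",
            length(cohort$patients))
  agreement <- per_patient_agreement(cohort, tol = config$staple_tol,
                                     max_iter = config$staple_max_iter)
  volume_cmp <- compare_volumes(cohort)
  dsc_test <- compare_disciplines_dsc(agreement)
  stage_log(quiet, "extract: feature panel")
  features <- extract_cohort_features(cohort, config$extraction)
  stage_log(quiet, "robustness: ICC(2,1)")
  icc_records <- feature_icc_table(features, threshold = config$icc_threshold)
  summary_tbl <- robust_summary(icc_records)
  cmp <- discipline_tables(icc_records, config$top_k)
  overlap <- cmp$overlap
  top_tbl <- cmp$top
  wilcoxon <- cmp$wilcoxon
  ranks <- cmp$ranks
  for (tbl in c("agreement", "volume_comparison", "dsc_test", "features",
                "icc_records"))
    write_table(get(c(agreement = "agreement",
                      volume_comparison = "volume_cmp",
                      dsc_test = "dsc_test", features = "features",
                      icc_records = "icc_records")[[tbl]]),
                file.path(tables, paste0(tbl, ".tsv")))
  write_table(summary_tbl, file.path(tables, "robust_summary.tsv"))
  write_table(top_tbl, file.path(tables, "top_features.tsv"))
  write_table(wilcoxon, file.path(tables, "wilcoxon.tsv"))
  write_table(ranks, file.path(tables, "rank_agreement.tsv"))
  structure(list(agreement = agreement, volume_comparison = volume_cmp,
                 dsc_test = dsc_test, features = features,
                 icc_records = icc_records, robust_summary = summary_tbl,
                 robust_intersection = overlap, top_features = top_tbl,
                 wilcoxon = wilcoxon, rank_agreement = ranks,
                 manifest = NULL, out_dir = out_dir, config = config),
            class = "segrobust_report")
}

#' @export
print.segrobust_report <- function(x, ...) {
  cat("<segrobust_report>\n")
  cat(sprintf("  %d patients, %d observer masks, %d features\n",
              length(unique(x$agreement$patient_id)), nrow(x$agreement),
              length(unique(x$features$feature_id))))
  sm <- x$agreement |>
    dplyr::group_by(.data$discipline) |>
    dplyr::summarise(m = mean(.data$dsc), s = stats::sd(.data$dsc))
  for (i in seq_len(nrow(sm)))
    cat(sprintf("  mean DSC (%s): %.3f +/- %.3f\n", sm$discipline[i],
                sm$m[i], sm$s[i]))
  rob <- x$icc_records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$robust))
  cat(sprintf("  robust features: %s; shared A&B: %d\n",
              paste(sprintf("%s=%d", rob$group, rob$n), collapse = ", "),
              x$robust_intersection))
  cat(sprintf("  tables under %s\n", x$out_dir))
  invisible(x)
}
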
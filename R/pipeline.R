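# Pipeline orchestration: file-based entry points tying the modules
# together (simulate, derive features, fit, transfer, persistence screen,
# confounder analysis, demographics table). Every artifact is CSV or JSON
# and carries a provenance echo (seed, settings, package version). A thin
# command-line wrapper over these functions ships in inst/cli/persimmune.R.

write_provenance <- function(path, step, seed, settings = list()) {
  jsonlite::write_json(list(
    step = step, seed = seed,
    package = "persimmune",
    version = as.character(utils::packageVersion("persimmune")),
    settings = settings
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Simulate a synthetic cohort to disk
#'
#' Writes the sample-level feature table, metadata and (optionally) the
#' cell-level event table as CSV, plus a provenance JSON echoing the
#' generator settings.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if missing).
#' @param events also simulate and write the event-level table
#'   (default FALSE; the sample-level table is the modeling substrate).
#' @return invisible named vector of written paths.
#' @export
run_simulate <- function(config, out_dir, events = FALSE) {
  ensure_dir(out_dir)
  gen <- generate_feature_table(config)
  paths <- c(features = file.path(out_dir, "features.csv"),
             metadata = file.path(out_dir, "metadata.csv"),
             provenance = file.path(out_dir, "provenance.json"))
  write_feature_table(gen$features, paths[["features"]])
  utils::write.csv(gen$metadata, paths[["metadata"]], row.names = FALSE)
  if (events) {
    ev <- generate_events(config)
    paths[["events"]] <- file.path(out_dir, "events.csv")
    utils::write.csv(ev$events, paths[["events"]], row.names = FALSE)
  }
  write_provenance(paths[["provenance"]], "simulate", config$seed,
                   settings = list(cohort = config$cohort,
                                   n_cases = config$n_cases,
                                   n_controls = config$n_controls,
                                   strata_sizes = as.list(
                                     config$strata_sizes)))
  invisible(paths)
}

read_metadata_outcome <- function(metadata_path) {
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!"outcome" %in% names(md)) {
    stop("metadata is missing required column: outcome", call. = FALSE)
  }
  md
}

align_features_metadata <- function(features, metadata) {
  if (!setequal(features$sample_id, metadata$sample_id)) {
    stop("feature table and metadata cover different samples", call. = FALSE)
  }
  metadata[match(features$sample_id, metadata$sample_id), , drop = FALSE]
}

#' Fit and cross-validate classifiers for one cohort from files
#'
#' Reads a feature CSV and metadata CSV, runs [select_best_model()] over the
#' candidate specifications, and writes the cv report (JSON), per-repeat
#' AUROCs (CSV) and the final model fit (JSON).
#'
#' @param features_path,metadata_path input CSVs.
#' @param out_dir output directory.
#' @param candidates list of [model_spec()] (default: early-fusion lasso).
#' @param cv a [cv_config()].
#' @return invisibly, the winning `cv_report`.
#' @export
run_fit <- function(features_path, metadata_path, out_dir,
                    candidates = list(model_spec("lasso")),
                    cv = cv_config()) {
  ensure_dir(out_dir)
  features <- read_feature_table(features_path)
  metadata <- align_features_metadata(features,
                                      read_metadata_outcome(metadata_path))
  report <- select_best_model(candidates, features, metadata$outcome, cv)
  write_cv_report(report, file.path(out_dir, "cv_report.json"))
  utils::write.csv(data.frame(repeat_index =
                                seq_along(report$auroc_per_repeat),
                              auroc = report$auroc_per_repeat),
                   file.path(out_dir, "auroc_per_repeat.csv"),
                   row.names = FALSE)
  write_model_fit(report$final_fit, file.path(out_dir, "model_fit.json"))
  write_provenance(file.path(out_dir, "provenance.json"), "fit", cv$seed,
                   settings = list(n_repeats = cv$n_repeats,
                                   n_folds = cv$n_folds,
                                   candidates = vapply(candidates, `[[`,
                                                       character(1),
                                                       "estimator")))
  invisible(report)
}

#' Transfer a trained model to a later cohort from files
#'
#' @param report a `cv_report` (in memory) whose final fit is transferred.
#' @param features_path,metadata_path target-cohort CSVs.
#' @param out_dir output directory.
#' @return invisibly, the [transfer_evaluate()] result.
#' @export
run_transfer <- function(report, features_path, metadata_path, out_dir) {
  ensure_dir(out_dir)
  features <- read_feature_table(features_path)
  metadata <- align_features_metadata(features,
                                      read_metadata_outcome(metadata_path))
  res <- transfer_evaluate(report$final_fit, features, metadata$outcome)
  jsonlite::write_json(list(auroc = res$auroc, p_value = res$p_value),
                       file.path(out_dir, "transfer.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(out_dir, "provenance.json"), "transfer",
                   report$cv$seed)
  invisible(res)
}

#' Persistence screen across cohorts from files
#'
#' Runs [univariate_screen()] per cohort and [persistence_venn()] across
#' them; writes per-feature results (CSV) and Venn region counts (JSON).
#'
#' @param cohort_paths named list: cohort -> list(features =, metadata =).
#' @param out_dir output directory.
#' @param alpha screen threshold (default 0.05, unadjusted).
#' @return invisibly, the `persistence_report`.
#' @export
run_persist <- function(cohort_paths, out_dir, alpha = 0.05) {
  ensure_dir(out_dir)
  screens <- lapply(cohort_paths, function(p) {
    features <- read_feature_table(p$features)
    metadata <- align_features_metadata(features,
                                        read_metadata_outcome(p$metadata))
    univariate_screen(features, metadata$outcome, alpha)
  })
  report <- persistence_venn(screens)
  long <- do.call(rbind, lapply(names(screens), function(co) {
    cbind(cohort = co, screens[[co]])
  }))
  utils::write.csv(long, file.path(out_dir, "screen_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(region_counts = as.list(report$region_counts),
                            shared_features = report$shared),
                       file.path(out_dir, "venn.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(out_dir, "provenance.json"), "persist", NA,
                   settings = list(alpha = alpha))
  invisible(report)
}

#' Confounder analysis of a cv report from files
#'
#' @param report a `cv_report` (its per-sample out-of-fold probabilities are
#'   the predictions under test).
#' @param metadata_path metadata CSV with the confounder columns.
#' @param out_dir output directory.
#' @param confounders confounder column names.
#' @return invisibly, the [confounder_adjustment()] result.
#' @export
run_confound <- function(report, metadata_path, out_dir,
                         confounders = c("bmi", "parity", "age",
                                         "gestational_diabetes",
                                         "systolic_bp", "diastolic_bp",
                                         "visit_timing")) {
  ensure_dir(out_dir)
  metadata <- read_metadata_outcome(metadata_path)
  res <- confounder_adjustment(report$oof_probability, metadata$outcome,
                               metadata[, confounders, drop = FALSE])
  jsonlite::write_json(list(terms = res$terms,
                            prediction_p = res$prediction_p,
                            still_predictive = res$still_predictive,
                            aux_f_tests = res$aux_f_tests,
                            separation = res$separation),
                       file.path(out_dir, "confounders.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_provenance(file.path(out_dir, "provenance.json"), "confound",
                   report$cv$seed)
  invisible(res)
}

#' Demographics comparison table from files
#'
#' @param metadata_path metadata CSV (raw per-sample demographics), or NULL
#'   to use the built-in published summaries.
#' @param out_dir output directory.
#' @return invisibly, the comparison data.frame.
#' @export
run_table2 <- function(metadata_path = NULL, out_dir) {
  ensure_dir(out_dir)
  tab <- if (is.null(metadata_path)) {
    build_table2_from_summaries()
  } else {
    build_table2(utils::read.csv(metadata_path, stringsAsFactors = FALSE))
  }
  utils::write.csv(tab, file.path(out_dir, "table2.csv"), row.names = FALSE)
  write_provenance(file.path(out_dir, "provenance.json"), "table2", NA)
  invisible(tab)
}
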
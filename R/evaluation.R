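# Repeated stratified cross-validation with AUROC and Mann-Whitney
# significance, model selection across candidate specifications, and
# cross-cohort model transfer.

#' Cross-validation settings
#'
#' Repeated stratified k-fold cross-validation: each fold holds out 1/k of
#' the samples (80%/20% at the default 5 folds), repeated `n_repeats` times
#' with reshuffled fold assignments.
#'
#' @param n_repeats number of repeats (study default 200; analyses in the
#'   test suite use 20).
#' @param n_folds folds per repeat (default 5; >= 2).
#' @param stratified stratify folds by outcome (default TRUE; small cohorts
#'   make unstratified splits class-degenerate with nontrivial probability).
#' @param alpha significance threshold for the Mann-Whitney verdict (0.05).
#' @param seed base seed of the fold stream; the same seed yields identical
#'   fold assignments across candidate models.
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_repeats = 200L, n_folds = 5L, stratified = TRUE,
                      alpha = 0.05, seed = 1L) {
  n_repeats <- stopifnot_scalar_count(n_repeats, "n_repeats")
  n_folds <- stopifnot_scalar_count(n_folds, "n_folds")
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  structure(list(n_repeats = n_repeats, n_folds = n_folds,
                 stratified = stratified, alpha = alpha,
                 seed = as.integer(seed)),
            class = "cv_config")
}

subset_samples <- function(table, idx) {
  if (is.list(table) && !is.data.frame(table)) {
    return(lapply(table, function(t) t[idx, , drop = FALSE]))
  }
  table[idx, , drop = FALSE]
}

n_samples_of <- function(table) {
  if (is.list(table) && !is.data.frame(table)) {
    return(nrow(table[[1L]]))
  }
  nrow(table)
}

#' Repeated cross-validated evaluation of a classifier
#'
#' For each repeat, draws a seeded stratified k-fold split, fits the
#' specified model on each training fold and collects out-of-fold predicted
#' probabilities for every sample; the per-repeat AUROC is computed on the
#' pooled out-of-fold predictions. The summary AUROC is the median across
#' repeats with a 2.5%-97.5% quantile interval; significance is the
#' two-sided Mann-Whitney p comparing cases' and controls' per-sample median
#' out-of-fold probabilities. A final fit on the whole dataset provides the
#' reported feature set.
#'
#' @param table feature table, or a named list of per-stratum tables (the
#'   fusion strategy of `spec` then applies).
#' @param labels binary outcome.
#' @param spec a [model_spec()].
#' @param cv a [cv_config()].
#' @return a `cv_report`: `auroc` (median), `auroc_interval`,
#'   `auroc_per_repeat`, `oof_probability` (per-sample median), `p_value`,
#'   `significant`, `final_fit`, `spec`, `cv`.
#' @export
repeated_cv <- function(table, labels, spec = model_spec(),
                        cv = cv_config()) {
  y <- as_binary_outcome(labels)
  n <- n_samples_of(table)
  stopifnot(length(y) == n)
  if (min(base::table(factor(y, levels = c(0L, 1L)))) < cv$n_folds) {
    stop("each class must have at least n_folds samples", call. = FALSE)
  }
  oof <- matrix(NA_real_, nrow = n, ncol = cv$n_repeats)
  aucs <- numeric(cv$n_repeats)
  for (r in seq_len(cv$n_repeats)) {
    rseed <- child_seed(cv$seed, r)
    folds <- if (cv$stratified) {
      stratified_folds(y, cv$n_folds, rseed)
    } else {
      with_seed(rseed, sample(rep_len(seq_len(cv$n_folds), n)))
    }
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- fit_model(subset_samples(table, tr), y[tr], spec,
                       seed = child_seed(rseed, f))
      oof[!tr, r] <- predict(fit, subset_samples(table, !tr))
    }
    aucs[r] <- auroc(oof[, r], y)
  }
  agg <- apply(oof, 1L, stats::median)
  p <- mann_whitney_p(agg[y == 1L], agg[y == 0L])
  final <- fit_model(table, y, spec, seed = child_seed(cv$seed, 0L))
  structure(list(
    auroc = stats::median(aucs),
    auroc_interval = stats::quantile(aucs, c(0.025, 0.975), names = FALSE),
    auroc_per_repeat = aucs,
    oof_probability = agg,
    p_value = p,
    significant = p < cv$alpha,
    final_fit = final,
    labels = y, spec = spec, cv = cv
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "Cross-validated %s (%s fusion)\n  AUROC (median of %d repeats): %.3f [%.3f, %.3f]\n  Mann-Whitney p: %.3g%s\n  Selected features: %d\n",
    x$spec$estimator, x$spec$fusion %||% "early", length(x$auroc_per_repeat),
    x$auroc, x$auroc_interval[1L], x$auroc_interval[2L], x$p_value,
    if (x$significant) " (significant)" else "",
    length(selected_features(x$final_fit))))
  invisible(x)
}

#' Select the best candidate model by cross-validated AUROC
#'
#' Runs [repeated_cv()] for every candidate specification with a shared fold
#' stream (identical splits across candidates) and returns the report with
#' the highest median AUROC. Ties break toward the sparser final model, then
#' toward the earlier candidate.
#'
#' @param candidates list of [model_spec()] objects.
#' @inheritParams repeated_cv
#' @return the winning `cv_report`, with `candidate_aurocs` attached.
#' @export
select_best_model <- function(candidates, table, labels,
                              cv = cv_config()) {
  if (length(candidates) == 0L) {
    stop("candidate list must be non-empty", call. = FALSE)
  }
  reports <- lapply(candidates, function(spec) {
    repeated_cv(table, labels, spec, cv)
  })
  aurocs <- vapply(reports, `[[`, numeric(1), "auroc")
  sizes <- vapply(reports, function(r) {
    length(selected_features(r$final_fit))
  }, numeric(1))
  ord <- order(-aurocs, sizes, seq_along(reports))
  best <- reports[[ord[1L]]]
  best$candidate_aurocs <- data.frame(
    estimator = vapply(candidates, `[[`, character(1), "estimator"),
    fusion = vapply(candidates, `[[`, character(1), "fusion"),
    auroc = aurocs, n_selected = sizes, stringsAsFactors = FALSE)
  best
}

#' Transfer a fitted model to a later cohort
#'
#' Applies a trained model to an independent target cohort without
#' refitting and reports the AUROC and two-sided Mann-Whitney p of the
#' predictions against the target labels.
#'
#' @param fit an `immune_fit` (e.g. a cv_report's `final_fit`).
#' @param target_table feature table carrying every training feature id.
#' @param target_labels binary outcome of the target cohort.
#' @return list with `auroc`, `p_value`, `predictions`.
#' @export
transfer_evaluate <- function(fit, target_table, target_labels) {
  y <- as_binary_outcome(target_labels)
  pred <- predict(fit, target_table)
  list(auroc = auroc(pred, y),
       p_value = mann_whitney_p(pred[y == 1L], pred[y == 0L]),
       predictions = pred)
}

#' Serialize a cv_report to JSON
#'
#' @param report a `cv_report`.
#' @param path file path.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(list(
    auroc_median = report$auroc,
    auroc_interval = report$auroc_interval,
    auroc_per_repeat = report$auroc_per_repeat,
    p_value = report$p_value,
    significant = report$significant,
    n_repeats = report$cv$n_repeats,
    n_folds = report$cv$n_folds,
    estimator = report$spec$estimator,
    fusion = report$spec$fusion %||% "early",
    selected_features = selected_features(report$final_fit),
    oof_probability = report$oof_probability
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
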
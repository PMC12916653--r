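# Sparse logistic case/control classifiers: lasso, adaptive lasso,
# decoy-calibrated stability selection, and early/late fusion of
# stimulation strata. Penalized fits are delegated to glmnet; penalty
# strength is chosen by inner stratified cross-validation maximizing AUROC,
# computed strictly within training data.

#' Classifier specification
#'
#' @param estimator one of "lasso", "adaptive_lasso", "stabl_lasso",
#'   "stabl_adaptive_lasso".
#' @param fusion "early" (one model on all strata concatenated) or "late"
#'   (per-stratum models combined by a second-stage logistic model on
#'   out-of-fold predicted probabilities); only used by [fit_fused()].
#' @param n_lambda points on the log-spaced regularization path (default 50).
#' @param inner_folds folds of the inner stratified CV that picks the
#'   penalty by pooled out-of-fold AUROC (default 5).
#' @param lambda optional fixed penalty; skips the inner CV.
#' @param gamma,epsilon adaptive-lasso weighting `w = 1/(|b0|^gamma + eps)`
#'   from a ridge initial fit (defaults 1, 1e-8); `gamma = 0` reduces to the
#'   plain lasso.
#' @param n_subsamples,subsample_fraction stability-selection subsampling
#'   (defaults 50 half-subsamples drawn without replacement).
#' @param selection_threshold optional fixed selection-frequency threshold;
#'   by default the threshold is chosen by minimizing the decoy-based
#'   false-discovery proportion proxy.
#' @param max_fdp when the minimized FDP proxy exceeds this cap the
#'   stability-selected model is empty (default 0.3).
#' @param refit_lambda ridge penalty of the final refit on the
#'   frequency-thresholded feature set (default 0.01).
#' @param standardize standardize features on training statistics before
#'   penalization (default TRUE).
#' @param seed integer seed for inner folds, subsamples and decoys.
#' @return a `model_spec` list.
#' @export
model_spec <- function(estimator = c("lasso", "adaptive_lasso",
                                     "stabl_lasso", "stabl_adaptive_lasso"),
                       fusion = c("early", "late"),
                       n_lambda = 50L, inner_folds = 5L, lambda = NULL,
                       gamma = 1, epsilon = 1e-8,
                       n_subsamples = 50L, subsample_fraction = 0.5,
                       selection_threshold = NULL, max_fdp = 0.3,
                       refit_lambda = 0.01,
                       standardize = TRUE, seed = 1L) {
  estimator <- match.arg(estimator)
  fusion <- match.arg(fusion)
  if (subsample_fraction <= 0 || subsample_fraction >= 1) {
    stop("subsample_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_subsamples < 2L) stop("n_subsamples must be >= 2", call. = FALSE)
  structure(list(estimator = estimator, fusion = fusion,
                 n_lambda = as.integer(n_lambda),
                 inner_folds = as.integer(inner_folds), lambda = lambda,
                 gamma = gamma, epsilon = epsilon,
                 n_subsamples = as.integer(n_subsamples),
                 subsample_fraction = subsample_fraction,
                 selection_threshold = selection_threshold,
                 max_fdp = max_fdp, refit_lambda = refit_lambda,
                 standardize = standardize, seed = as.integer(seed)),
            class = "model_spec")
}

# Column-concatenate per-stratum feature tables (same samples, same order).
merge_strata <- function(tables) {
  do.call(cbind, c(list(tables[[1L]]["sample_id"]),
                   lapply(unname(tables), function(t) {
                     t[, -1L, drop = FALSE]
                   })))
}

check_modeling_inputs <- function(x, y) {
  counts <- base::table(factor(y, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  invisible(NULL)
}

drop_constant_columns <- function(x) {
  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature column(s): ",
            paste(utils::head(colnames(x)[const], 3L), collapse = ", "),
            if (sum(const) > 3L) ", ...", call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  x
}

new_immune_fit <- function(estimator, intercept, coef, features, spec,
                           lambda = NA_real_, dropped = character(0),
                           extra = list()) {
  structure(c(list(estimator = estimator, intercept = as.numeric(intercept),
                   coef = coef, features = features, lambda = lambda,
                   dropped = dropped, spec = spec), extra),
            class = "immune_fit")
}

intercept_only_fit <- function(y, estimator, features, spec) {
  new_immune_fit(estimator, stats::qlogis(mean(y) + 1e-12) , numeric(0),
                 features, spec)
}

# Pooled out-of-fold AUROC over a fixed lambda path; folds, standardization
# and the path are all computed within the supplied (training) data only.
inner_cv_lambda <- function(x, y, path, spec, seed, alpha = 1,
                            penalty_factor = rep(1, ncol(x))) {
  folds <- stratified_folds(y, spec$inner_folds, seed)
  eta <- matrix(NA_real_, nrow = length(y), ncol = length(path))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    fit <- quiet_glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = alpha, lambda = path,
                          standardize = spec$standardize,
                          penalty.factor = penalty_factor)
    eta[!tr, ] <- stats::predict(fit, x[!tr, , drop = FALSE], s = path,
                                 type = "link")
  }
  ok <- stats::complete.cases(eta)
  aucs <- apply(eta[ok, , drop = FALSE], 2L, auroc, labels = y[ok])
  # ties break toward the larger penalty (path is decreasing): first max
  path[which.max(aucs)]
}

glmnet_path <- function(x, y, spec, alpha = 1,
                        penalty_factor = rep(1, ncol(x))) {
  g <- quiet_glmnet(x, y, family = "binomial", alpha = alpha,
                      nlambda = spec$n_lambda, standardize = spec$standardize,
                      penalty.factor = penalty_factor)
  g$lambda
}

coef_vector <- function(fit, s, features) {
  cf <- as.numeric(stats::coef(fit, s = s))
  names(cf) <- c("(Intercept)", features)
  cf
}

fit_penalized <- function(x, y, spec, seed, alpha = 1,
                          penalty_factor = rep(1, ncol(x)), estimator) {
  if (!is.null(spec$lambda)) {
    lambda_star <- spec$lambda
    path <- sort(unique(c(lambda_star, glmnet_path(x, y, spec, alpha,
                                                   penalty_factor))),
                 decreasing = TRUE)
  } else {
    path <- glmnet_path(x, y, spec, alpha, penalty_factor)
    lambda_star <- inner_cv_lambda(x, y, path, spec, seed, alpha,
                                   penalty_factor)
  }
  final <- quiet_glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = path, standardize = spec$standardize,
                          penalty.factor = penalty_factor)
  cf <- coef_vector(final, lambda_star, colnames(x))
  beta <- cf[-1L]
  new_immune_fit(estimator, cf[1L], beta[beta != 0], colnames(x), spec,
                 lambda = lambda_star)
}

#' Fit an L1-penalized (lasso) logistic classifier
#'
#' Penalty strength is chosen by inner stratified cross-validation
#' maximizing pooled out-of-fold AUROC over a log-spaced path; features are
#' standardized on training statistics inside glmnet. Constant columns are
#' dropped with a warning.
#'
#' @param table feature table (`sample_id` first column) or numeric matrix.
#' @param labels binary outcome.
#' @param spec a [model_spec()].
#' @param seed seed for the inner folds (default from `spec`).
#' @return an `immune_fit`: sparse coefficients, intercept, selected
#'   features (`selected_features()`), training feature ids.
#' @export
fit_lasso <- function(table, labels, spec = model_spec("lasso"),
                      seed = spec$seed) {
  x <- feature_matrix(table)
  y <- as_binary_outcome(labels)
  check_modeling_inputs(x, y)
  x2 <- drop_constant_columns(x)
  dropped <- setdiff(colnames(x), colnames(x2))
  fit <- fit_penalized(x2, y, spec, seed, alpha = 1, estimator = "lasso")
  fit$dropped <- dropped
  fit
}

#' Fit an adaptive-lasso logistic classifier
#'
#' Two-stage fit: a ridge initial fit gives coefficients `b0`, per-feature
#' weights `w = 1/(|b0|^gamma + epsilon)` then rescale the L1 penalty
#' (features with zero initial signal are effectively never selected);
#' the weighted lasso penalty is chosen by the same inner CV as [fit_lasso()].
#'
#' @inheritParams fit_lasso
#' @export
fit_adaptive_lasso <- function(table, labels,
                               spec = model_spec("adaptive_lasso"),
                               seed = spec$seed) {
  x <- feature_matrix(table)
  y <- as_binary_outcome(labels)
  check_modeling_inputs(x, y)
  x2 <- drop_constant_columns(x)
  dropped <- setdiff(colnames(x), colnames(x2))
  ridge_path <- glmnet_path(x2, y, spec, alpha = 0)
  ridge_lambda <- inner_cv_lambda(x2, y, ridge_path, spec,
                                  child_seed(seed, 11L), alpha = 0)
  ridge <- quiet_glmnet(x2, y, family = "binomial", alpha = 0,
                          lambda = ridge_path,
                          standardize = spec$standardize)
  b0 <- coef_vector(ridge, ridge_lambda, colnames(x2))[-1L]
  w <- 1 / (abs(b0)^spec$gamma + spec$epsilon)
  fit <- fit_penalized(x2, y, spec, child_seed(seed, 12L), alpha = 1,
                       penalty_factor = w, estimator = "adaptive_lasso")
  fit$dropped <- dropped
  fit$initial_coef <- b0
  fit
}

#' Fit a stability-selected sparse logistic classifier
#'
#' Decoy-calibrated stability selection: the base sparse estimator is fit on
#' `n_subsamples` half-subsamples of the training data with one
#' label-independent permutation decoy appended per real feature; each
#' feature's selection frequency is its maximal per-lambda selection
#' proportion along a shared path. The selection-frequency threshold
#' minimizes the decoy-based false-discovery proportion proxy
#' `(1 + #decoys >= t) / max(1, #real >= t)`; if the minimized proxy exceeds
#' `max_fdp` the model is empty. Features passing the threshold are refit
#' with a ridge-stabilized logistic model.
#'
#' @inheritParams fit_lasso
#' @return an `immune_fit` with `selection_frequency`, `threshold` and
#'   `min_fdp` recorded.
#' @export
fit_stability_selected <- function(table, labels,
                                   spec = model_spec("stabl_lasso"),
                                   seed = spec$seed) {
  x <- feature_matrix(table)
  y <- as_binary_outcome(labels)
  check_modeling_inputs(x, y)
  x <- drop_constant_columns(x)
  p <- ncol(x)
  decoys <- with_seed(child_seed(seed, 21L), {
    apply(x, 2L, sample)
  })
  colnames(decoys) <- paste0(".decoy.", colnames(x))
  xa <- cbind(x, decoys)
  penalty_factor <- rep(1, 2L * p)
  if (spec$estimator == "stabl_adaptive_lasso") {
    ridge_path <- glmnet_path(xa, y, spec, alpha = 0)
    ridge_lambda <- inner_cv_lambda(xa, y, ridge_path, spec,
                                    child_seed(seed, 22L), alpha = 0)
    ridge <- quiet_glmnet(xa, y, family = "binomial", alpha = 0,
                            lambda = ridge_path,
                            standardize = spec$standardize)
    b0 <- coef_vector(ridge, ridge_lambda, colnames(xa))[-1L]
    penalty_factor <- 1 / (abs(b0)^spec$gamma + spec$epsilon)
  }
  path <- glmnet_path(xa, y, spec, alpha = 1, penalty_factor)
  sel <- matrix(0, nrow = 2L * p, ncol = length(path))
  n_sub <- 0L
  for (b in seq_len(spec$n_subsamples)) {
    idx <- with_seed(child_seed(seed, 100L + b), {
      unlist(lapply(c(0L, 1L), function(cls) {
        cls_idx <- which(y == cls)
        sample(cls_idx, max(2L, round(spec$subsample_fraction *
                                        length(cls_idx))))
      }))
    })
    if (length(unique(y[idx])) < 2L) next
    g <- quiet_glmnet(xa[idx, , drop = FALSE], y[idx],
                        family = "binomial", alpha = 1, lambda = path,
                        standardize = spec$standardize,
                        penalty.factor = penalty_factor)
    bm <- as.matrix(g$beta != 0)
    if (ncol(bm) < length(path)) {
      bm <- cbind(bm, matrix(bm[, ncol(bm)], nrow = nrow(bm),
                             ncol = length(path) - ncol(bm)))
    }
    sel <- sel + bm
    n_sub <- n_sub + 1L
  }
  freq <- apply(sel / n_sub, 1L, max)
  freq_real <- freq[seq_len(p)]
  freq_decoy <- freq[p + seq_len(p)]
  names(freq_real) <- colnames(x)
  grid <- seq(0.05, 1, by = 0.01)
  fdp <- vapply(grid, function(t) {
    (1 + sum(freq_decoy >= t)) / max(1, sum(freq_real >= t))
  }, numeric(1))
  min_fdp <- min(fdp)
  if (!is.null(spec$selection_threshold)) {
    threshold <- spec$selection_threshold
    selected <- names(freq_real)[freq_real >= threshold]
  } else {
    threshold <- max(grid[fdp == min_fdp])   # ties toward the stricter cut
    selected <- if (min_fdp <= spec$max_fdp) {
      names(freq_real)[freq_real >= threshold]
    } else character(0)
  }
  fit <- logistic_refit(x[, selected, drop = FALSE], y, spec)
  new_immune_fit(spec$estimator, fit$intercept, fit$coef, colnames(x), spec,
                 extra = list(selection_frequency = freq_real,
                              decoy_frequency = unname(freq_decoy),
                              threshold = threshold, min_fdp = min_fdp))
}

# Ridge-stabilized logistic refit on a (possibly empty or single-column)
# selected feature set.
logistic_refit <- function(x, y, spec) {
  if (ncol(x) == 0L) {
    return(list(intercept = stats::qlogis((sum(y) + 0.5) /
                                            (length(y) + 1)),
                coef = numeric(0)))
  }
  if (ncol(x) == 1L) {
    d <- data.frame(y = y, v = x[, 1L])
    g <- suppressWarnings(stats::glm(y ~ v, data = d, family = "binomial"))
    cf <- stats::coef(g)
    beta <- cf[-1L]
    names(beta) <- colnames(x)
    return(list(intercept = cf[[1L]], coef = beta))
  }
  g <- quiet_glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = spec$refit_lambda, standardize = FALSE)
  cf <- coef_vector(g, spec$refit_lambda, colnames(x))
  list(intercept = cf[1L], coef = cf[-1L])
}

#' Fit a classifier by specification
#'
#' Dispatches on `spec$estimator`; accepts a single feature table or a named
#' list of per-stratum tables (dispatched to [fit_fused()]).
#'
#' @inheritParams fit_lasso
#' @export
fit_model <- function(table, labels, spec = model_spec(), seed = spec$seed) {
  if (is.list(table) && !is.data.frame(table)) {
    return(fit_fused(table, labels, spec, seed))
  }
  switch(spec$estimator,
    lasso = fit_lasso(table, labels, spec, seed),
    adaptive_lasso = fit_adaptive_lasso(table, labels, spec, seed),
    stabl_lasso = ,
    stabl_adaptive_lasso = fit_stability_selected(table, labels, spec, seed))
}

#' Fit with early or late fusion of stimulation strata
#'
#' Early fusion concatenates the column-disjoint strata and fits one model.
#' Late fusion fits the base estimator per stratum, collects out-of-fold
#' predicted probabilities from an internal stratified 5-fold split (so the
#' combiner never sees in-fold predictions), trains a logistic combiner on
#' them, and refits each stratum on the full data for prediction.
#'
#' @param tables named list: stratum -> feature table, same samples in the
#'   same order in each.
#' @inheritParams fit_lasso
#' @export
fit_fused <- function(tables, labels, spec = model_spec(),
                      seed = spec$seed) {
  if (!is.list(tables) || length(tables) == 0L) {
    stop("`tables` must be a non-empty named list of feature tables",
         call. = FALSE)
  }
  sample_sets <- lapply(tables, function(t) as.character(t$sample_id))
  if (!all(vapply(sample_sets, identical, logical(1), sample_sets[[1L]]))) {
    stop("sample sets differ across strata", call. = FALSE)
  }
  all_cols <- unlist(lapply(tables, function(t) names(t)[-1L]))
  if (anyDuplicated(all_cols)) {
    stop("strata must be column-disjoint", call. = FALSE)
  }
  y <- as_binary_outcome(labels)
  if (spec$fusion == "early") {
    fit <- fit_model(merge_strata(tables), y, spec, seed)
    fit$fusion <- "early"
    return(fit)
  }
  k <- 5L
  folds <- stratified_folds(y, k, child_seed(seed, 31L))
  oof <- matrix(NA_real_, nrow = length(y), ncol = length(tables),
                dimnames = list(NULL, names(tables)))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    for (s in seq_along(tables)) {
      fit_s <- fit_model(tables[[s]][tr, , drop = FALSE], y[tr], spec,
                         child_seed(seed, 40L + 10L * s + f))
      oof[!tr, s] <- predict(fit_s, tables[[s]][!tr, , drop = FALSE])
    }
  }
  combiner <- logistic_refit(stats::qlogis(pmin(pmax(oof, 1e-6), 1 - 1e-6)),
                             y, spec)
  layer_fits <- lapply(seq_along(tables), function(s) {
    fit_model(tables[[s]], y, spec, child_seed(seed, 90L + s))
  })
  names(layer_fits) <- names(tables)
  sel <- unlist(lapply(layer_fits, selected_features), use.names = FALSE)
  new_immune_fit(spec$estimator, combiner$intercept, numeric(0),
                 unlist(lapply(tables, function(t) names(t)[-1L]),
                        use.names = FALSE),
                 spec,
                 extra = list(fusion = "late",
                              layers = layer_fits,
                              combiner = combiner,
                              selected_late = sel))
}

#' Selected (nonzero-coefficient) features of a fit
#'
#' @param fit an `immune_fit`.
#' @return character vector of feature ids.
#' @export
selected_features <- function(fit) {
  stopifnot(inherits(fit, "immune_fit"))
  if (identical(fit$fusion, "late")) return(fit$selected_late)
  names(fit$coef)[fit$coef != 0]
}

#' Predict case probabilities
#'
#' Deterministic probabilities for new samples; every training feature must
#' be present (missing columns are an error naming them; extra columns are
#' ignored with a warning).
#'
#' @param object an `immune_fit`.
#' @param newdata feature table or numeric matrix.
#' @param ... unused.
#' @return numeric probabilities in (0, 1), in input sample order.
#' @export
predict.immune_fit <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata)) {
    newdata <- merge_strata(newdata)
  }
  x <- feature_matrix(newdata)
  missing <- setdiff(object$features, colnames(x))
  if (length(missing) > 0L) {
    stop("newdata is missing required feature column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...", call. = FALSE)
  }
  extra <- setdiff(colnames(x), c(object$features, object$dropped))
  if (length(extra) > 0L) {
    warning(length(extra), " extra feature column(s) ignored", call. = FALSE)
  }
  if (identical(object$fusion, "late")) {
    probs <- vapply(object$layers, function(fit_s) {
      predict(fit_s, suppressWarnings(x[, fit_s$features, drop = FALSE]))
    }, numeric(nrow(x)))
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(x))
    eta <- stats::qlogis(pmin(pmax(probs, 1e-6), 1 - 1e-6))
    w <- object$combiner$coef
    lin <- object$intercept +
      as.numeric(eta[, names(w), drop = FALSE] %*% w)
    return(as.numeric(stats::plogis(lin)))
  }
  active <- names(object$coef)
  lin <- object$intercept +
    if (length(active) > 0L) {
      as.numeric(x[, active, drop = FALSE] %*% object$coef)
    } else 0
  as.numeric(stats::plogis(lin))
}

#' Serialize / restore a model fit as JSON
#'
#' Stores feature ids, coefficients, layer structure and the spec echo.
#'
#' @param fit an `immune_fit`.
#' @param path file path.
#' @export
write_model_fit <- function(fit, path) {
  ser <- function(f) {
    list(estimator = f$estimator, fusion = f$fusion %||% "single",
         intercept = f$intercept, coef = as.list(f$coef),
         features = f$features, lambda = f$lambda,
         threshold = f$threshold, seed = f$spec$seed,
         spec = f$spec[c("estimator", "fusion", "n_lambda", "inner_folds",
                         "gamma", "n_subsamples", "subsample_fraction",
                         "max_fdp")],
         layers = if (identical(f$fusion, "late")) {
           lapply(f$layers, ser)
         },
         combiner = if (identical(f$fusion, "late")) {
           list(intercept = f$combiner$intercept,
                coef = as.list(f$combiner$coef))
         })
  }
  jsonlite::write_json(ser(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
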
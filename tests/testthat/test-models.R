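# Sparse classifiers: lasso, adaptive lasso, stability selection, fusion,
# prediction contracts.

# n x p noise matrix with an optional perfectly separating first feature
noise_table <- function(seed, n = 100, p = 50, separate = FALSE) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  if (separate) x[, 1] <- y * 2 + rnorm(n, sd = 0.1)
  list(table = as_feature_table(x, sprintf("s%03d", seq_len(n))), y = y)
}

test_that("lasso finds a perfectly separating feature among noise", {
  hits <- vapply(1:20, function(seed) {
    d <- noise_table(seed, separate = TRUE)
    fit <- fit_lasso(d$table, d$y, model_spec("lasso", seed = seed))
    "f001" %in% selected_features(fit)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("an overwhelming penalty gives an intercept-only prevalence model", {
  d <- noise_table(1, n = 60)
  y <- c(rep(0L, 40), rep(1L, 20))
  fit <- fit_lasso(d$table, y, model_spec("lasso", lambda = 1e9))
  expect_length(selected_features(fit), 0)
  pred <- predict(fit, d$table)
  expect_equal(unique(pred), mean(y), tolerance = 1e-6)
})

test_that("single-class labels and missing values are rejected", {
  d <- noise_table(2, n = 20, p = 5)
  expect_error(fit_lasso(d$table, rep(1, 20)), "2 samples per class")
  d$table[3, 4] <- NA
  expect_error(fit_lasso(d$table, d$y), "missing values")
})

test_that("constant columns are dropped with a warning, not an error", {
  d <- noise_table(3, n = 60, p = 10, separate = TRUE)
  d$table[["f005"]] <- 7
  expect_warning(fit <- fit_lasso(d$table, d$y), "constant")
  expect_false("f005" %in% selected_features(fit))
  # prediction still works on tables carrying the constant column
  expect_silent(predict(fit, d$table))
})

test_that("adaptive lasso with gamma = 0 reduces to the plain lasso", {
  d <- noise_table(4, separate = TRUE)
  plain <- fit_lasso(d$table, d$y, model_spec("lasso", seed = 9))
  degen <- fit_adaptive_lasso(d$table, d$y,
                              model_spec("adaptive_lasso", gamma = 0,
                                         seed = 9))
  # unit weights: same estimator family; the separating feature agrees
  expect_true("f001" %in% selected_features(degen))
  expect_setequal(selected_features(degen), selected_features(plain))
})

test_that("adaptive weighting sparsifies relative to the plain lasso", {
  leq <- vapply(1:10, function(seed) {
    d <- noise_table(100 + seed, separate = TRUE)
    plain <- fit_lasso(d$table, d$y, model_spec("lasso", seed = seed))
    adapt <- fit_adaptive_lasso(d$table, d$y,
                                model_spec("adaptive_lasso", seed = seed))
    length(selected_features(adapt)) <= length(selected_features(plain))
  }, logical(1))
  expect_gte(mean(leq), 0.8)
})

test_that("the L1 path is monotone in support size", {
  d <- noise_table(5, separate = TRUE)
  sizes <- vapply(c(0.3, 0.1, 0.03, 0.01), function(lam) {
    fit <- fit_lasso(d$table, d$y, model_spec("lasso", lambda = lam))
    length(selected_features(fit))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))  # decreasing penalty, growing support
})

test_that("stability selection rejects pure noise and recovers planted signal", {
  null_sizes <- vapply(1:5, function(seed) {
    d <- noise_table(200 + seed, n = 80, p = 200)
    fit <- fit_stability_selected(d$table, d$y,
                                  model_spec("stabl_lasso", seed = seed))
    length(selected_features(fit))
  }, numeric(1))
  expect_gte(mean(null_sizes == 0), 0.8)

  recovered <- vapply(1:10, function(seed) {
    set.seed(300 + seed)
    n <- 80; p <- 200
    y <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(rnorm(n * p), nrow = n,
                dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
    x[, 1:5] <- x[, 1:5] + 2 * y   # standardized effect 2.0
    fit <- fit_stability_selected(as_feature_table(x, paste0("s", 1:n)), y,
                                  model_spec("stabl_lasso", seed = seed))
    all(sprintf("f%03d", 1:5) %in% selected_features(fit))
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("an unattainable selection threshold gives an empty model", {
  d <- noise_table(6, n = 60, p = 40, separate = TRUE)
  fit <- fit_stability_selected(
    d$table, d$y, model_spec("stabl_lasso", selection_threshold = 1.01))
  expect_length(selected_features(fit), 0)
})

test_that("late fusion of a single stratum matches early fusion closely", {
  g <- make_cohort(11, planted = planted_ten(1.5))
  strata <- split_strata(g$features)[c("Unstim")]
  cv <- cv_config(n_repeats = 5, seed = 3)
  early <- repeated_cv(g$features[, c(TRUE, grepl("^Unstim",
                                                  names(g$features)[-1]))],
                       g$y, model_spec("lasso", fusion = "early", seed = 1),
                       cv)
  late <- repeated_cv(strata, g$y,
                      model_spec("lasso", fusion = "late", seed = 1), cv)
  expect_lt(abs(early$auroc - late$auroc), 0.02)
})

test_that("a pure-noise stratum does not dilute late fusion", {
  g <- make_cohort(12, planted = planted_ten(2))
  strata <- split_strata(g$features)
  informative <- strata[["Unstim"]]
  cv <- cv_config(n_repeats = 5, seed = 4)
  alone <- repeated_cv(informative, g$y, model_spec("lasso", seed = 2), cv)
  # IL18 planted features removed so the stratum is noise-only
  noise <- strata[["IL18"]]
  noise <- noise[, !names(noise) %in% planted_ids(planted_ten(2)),
                 drop = FALSE]
  fused <- repeated_cv(list(Unstim = informative, IL18 = noise), g$y,
                       model_spec("lasso", fusion = "late", seed = 2), cv)
  expect_lt(abs(fused$auroc - alone$auroc), 0.05)
})

test_that("fusion input contracts are enforced", {
  g <- make_cohort(13)
  expect_error(fit_fused(list(), g$y), "non-empty")
  strata <- split_strata(g$features)
  bad <- strata
  bad[[2]] <- bad[[2]][rev(seq_len(nrow(bad[[2]]))), ]
  expect_error(fit_fused(bad, g$y), "sample sets differ")
})

test_that("prediction is deterministic, order-equivariant and guarded", {
  d <- noise_table(7, separate = TRUE)
  fit <- fit_lasso(d$table, d$y)
  p1 <- predict(fit, d$table)
  expect_identical(p1, predict(fit, d$table))
  perm <- sample(nrow(d$table))
  expect_identical(predict(fit, d$table[perm, ]), p1[perm])
  expect_error(predict(fit, d$table[, -2]), "f001")
  expect_warning(
    predict(fit, cbind(d$table, extra_col = 1)), "extra")
})

test_that("cross-validated predictions are scale-equivariant", {
  d <- noise_table(8, n = 60, p = 20, separate = TRUE)
  fit1 <- fit_lasso(d$table, d$y, model_spec("lasso", seed = 5))
  scaled <- d$table
  scaled[["f002"]] <- scaled[["f002"]] * 10
  fit2 <- fit_lasso(scaled, d$y, model_spec("lasso", seed = 5))
  expect_equal(predict(fit1, d$table), predict(fit2, scaled),
               tolerance = 1e-6)
})

test_that("training-fold models never see held-out samples", {
  d <- noise_table(9, n = 40, p = 15, separate = TRUE)
  cv <- cv_config(n_repeats = 1, n_folds = 5, seed = 21)
  folds <- persimmune:::stratified_folds(d$y, 5,
                                         persimmune:::child_seed(21, 1))
  r1 <- repeated_cv(d$table, d$y, model_spec("lasso", seed = 1), cv)
  # corrupt one sample massively; only folds training on it may change
  i <- which(folds == 1)[1]
  poisoned <- d$table
  poisoned[i, -1] <- poisoned[i, -1] + 1e3
  # the extreme outlier makes some training folds separable: glmnet path
  # convergence warnings are expected for this adversarial fixture
  r2 <- suppressWarnings(
    repeated_cv(poisoned, d$y, model_spec("lasso", seed = 1), cv))
  others_in_fold1 <- setdiff(which(folds == 1), i)
  expect_equal(r1$oof_probability[others_in_fold1],
               r2$oof_probability[others_in_fold1])
})

test_that("model fits serialize to JSON and back-read consistently", {
  d <- noise_table(10, n = 60, p = 10, separate = TRUE)
  fit <- fit_lasso(d$table, d$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_fit(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$estimator, "lasso")
  expect_equal(unlist(back$coef[["f001"]]), unname(fit$coef["f001"]),
               tolerance = 1e-12)
})
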
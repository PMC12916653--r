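# Downstream analyses: univariate case/control screens per cohort, Venn
# overlap of persistent features, confounder adjustment of model
# predictions, HDP-subtype stratification and CVD risk-factor correlation.

#' Univariate Mann-Whitney screen of a feature table
#'
#' Two-sided Mann-Whitney p per feature (the same implementation as the
#' model-evaluation significance test), direction as the sign of
#' (case median - control median), and a significance flag at `alpha`
#' without multiple-testing adjustment, mirroring the deliberately less
#' stringent univariate screen; Benjamini-Hochberg q-values are reported
#' alongside for transparency. Constant features get p = 1 and direction 0.
#'
#' @param table feature table (`sample_id` first column) or numeric matrix.
#' @param labels binary outcome.
#' @param alpha unadjusted significance threshold (default 0.05).
#' @return data.frame: `feature`, `p`, `q`, `direction` (-1/0/1),
#'   `significant`.
#' @export
univariate_screen <- function(table, labels, alpha = 0.05) {
  x <- feature_matrix(table)
  y <- as_binary_outcome(labels)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  res <- apply(x, 2L, function(v) {
    if (stats::sd(v) == 0) return(c(p = 1, direction = 0))
    c(p = mann_whitney_p(v[y == 1L], v[y == 0L]),
      direction = sign(stats::median(v[y == 1L]) -
                         stats::median(v[y == 0L])))
  })
  out <- data.frame(feature = colnames(x), p = res["p", ],
                    q = stats::p.adjust(res["p", ], method = "BH"),
                    direction = as.integer(res["direction", ]),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Venn overlap of significant features across cohorts
#'
#' Intersects the significant-feature sets of per-cohort screens and counts
#' the regions of the 3-set (or 2-set) Venn diagram. Features significant in
#' every cohort are reported with their per-cohort directions and a
#' direction-consistency flag.
#'
#' @param screens named list of [univariate_screen()] results (one per
#'   cohort) sharing the same feature vocabulary.
#' @return a `persistence_report`: `region_counts` (named by cohort-set,
#'   e.g. "AP&PP"), `sets` (significant ids per cohort), `shared` data.frame
#'   of features in the full intersection with per-cohort directions and
#'   `consistent` flag.
#' @export
persistence_venn <- function(screens) {
  stopifnot(length(screens) >= 2L, !is.null(names(screens)))
  vocab <- screens[[1L]]$feature
  for (s in screens) {
    if (!identical(sort(s$feature), sort(vocab))) {
      stop("screens have mismatched feature vocabularies", call. = FALSE)
    }
  }
  sets <- lapply(screens, function(s) s$feature[s$significant])
  cohorts <- names(screens)
  membership <- vapply(sets, function(s) vocab %in% s,
                       logical(length(vocab)))
  in_any <- rowSums(membership) > 0
  # one region per non-empty cohort subset
  patterns <- apply(membership[in_any, , drop = FALSE], 1L, function(m) {
    paste(cohorts[m], collapse = "&")
  })
  all_regions <- unlist(lapply(seq_along(cohorts), function(k) {
    apply(utils::combn(cohorts, k), 2L, paste, collapse = "&")
  }))
  region_counts <- vapply(all_regions, function(r) sum(patterns == r),
                          integer(1))
  shared_ids <- vocab[rowSums(membership) == length(cohorts)]
  shared <- data.frame(feature = shared_ids, stringsAsFactors = FALSE)
  for (co in cohorts) {
    s <- screens[[co]]
    shared[[paste0("direction_", co)]] <-
      s$direction[match(shared_ids, s$feature)]
  }
  if (nrow(shared) > 0L) {
    dirs <- as.matrix(shared[, -1L, drop = FALSE])
    shared$consistent <- apply(dirs, 1L, function(d) {
      length(unique(d)) == 1L
    })
  } else {
    shared$consistent <- logical(0)
  }
  structure(list(region_counts = region_counts, sets = sets,
                 shared = shared, cohorts = cohorts),
            class = "persistence_report")
}

#' Confounder adjustment of cross-validated predictions
#'
#' Fits the logistic model `outcome ~ prediction + confounders` and tests
#' each term by drop-one likelihood-ratio tests; the model "remains
#' significantly predictive" when the prediction term's p stays below
#' `alpha`. An auxiliary linear model `prediction ~ confounders` with
#' per-term F-tests is reported alongside. Rows with missing confounders
#' are dropped (count reported). Perfect separation triggers a
#' ridge-penalized refit and is flagged.
#'
#' @param predictions per-sample cross-validated case probabilities.
#' @param outcome binary outcome.
#' @param confounders data.frame of confounding variables.
#' @param alpha significance threshold for the verdict (default 0.05).
#' @return list: `terms` (per-term LRT data.frame), `prediction_p`,
#'   `still_predictive`, `aux_f_tests` (linear-model F per confounder),
#'   `n_dropped`, `separation`.
#' @export
confounder_adjustment <- function(predictions, outcome, confounders,
                                  alpha = 0.05) {
  y <- as_binary_outcome(outcome)
  confounders <- as.data.frame(confounders)
  d <- data.frame(.outcome = y, .prediction = as.numeric(predictions),
                  confounders, check.names = TRUE)
  ok <- stats::complete.cases(d)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message("dropping ", n_dropped, " sample(s) with missing confounders")
  }
  d <- d[ok, , drop = FALSE]
  full <- suppressWarnings(stats::glm(.outcome ~ ., data = d,
                                      family = "binomial"))
  separation <- any(full$fitted.values > 1 - 1e-8 |
                      full$fitted.values < 1e-8) || !full$converged
  if (separation) {
    lrt <- ridge_drop_one(d)
  } else {
    dr <- stats::drop1(full, test = "LRT")
    lrt <- data.frame(term = rownames(dr)[-1L],
                      statistic = dr$LRT[-1L],
                      p = dr[["Pr(>Chi)"]][-1L], stringsAsFactors = FALSE)
  }
  pred_p <- lrt$p[lrt$term == ".prediction"]
  aux <- NULL
  if (ncol(confounders) > 0L) {
    daux <- d[, setdiff(names(d), ".outcome"), drop = FALSE]
    lmfit <- stats::lm(.prediction ~ ., data = daux)
    dr <- stats::drop1(lmfit, test = "F")
    aux <- data.frame(term = rownames(dr)[-1L],
                      f_statistic = dr[["F value"]][-1L],
                      p = dr[["Pr(>F)"]][-1L], stringsAsFactors = FALSE)
  }
  list(terms = lrt, prediction_p = pred_p,
       still_predictive = pred_p < alpha,
       aux_f_tests = aux, n_dropped = n_dropped, separation = separation)
}

# Drop-one tests under a small ridge penalty: deviance differences between
# penalized refits, referred to chi-square. Used when the unpenalized
# logistic fit separates.
ridge_drop_one <- function(d, lambda = 1e-2) {
  y <- d$.outcome
  terms <- setdiff(names(d), ".outcome")
  xfull <- stats::model.matrix(~ . - 1, data = d[, terms, drop = FALSE])
  dev <- function(x) {
    if (ncol(x) < 2L) x <- cbind(x, 0)
    g <- quiet_glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda)
    eta <- stats::predict(g, x, s = lambda, type = "link")
    p <- stats::plogis(eta)
    -2 * sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  }
  dev_full <- dev(xfull)
  rows <- lapply(terms, function(tm) {
    cols <- grep(paste0("^", gsub("([.|()\\^{}+$*?\\[\\]\\\\])", "\\\\\\1",
                                  tm)), colnames(xfull))
    x0 <- xfull[, -cols, drop = FALSE]
    stat <- max(0, dev(x0) - dev_full)
    data.frame(term = tm, statistic = stat,
               p = stats::pchisq(stat, df = length(cols),
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subtype stratification of a persistent feature
#'
#' Mann-Whitney contrasts of a feature among cases only: early vs late
#' onset, mild vs severe preeclampsia, and gestational hypertension vs
#' preeclampsia/HELLP. Contrasts with an empty level are skipped with a
#' flag; groups below `min_n` are flagged under-powered.
#'
#' @param values named or metadata-aligned numeric feature values.
#' @param metadata metadata with `outcome`, `onset`, `pe_severity`,
#'   `hdp_subtype` columns (see [generate_confounders()]).
#' @param min_n per-group size below which a contrast is flagged
#'   under-powered (default 5).
#' @return data.frame: `contrast`, `n1`, `n2`, `p`, `skipped`,
#'   `underpowered`.
#' @export
subtype_stratify <- function(values, metadata, min_n = 5L) {
  stopifnot(length(values) == nrow(metadata))
  cases <- as_binary_outcome(metadata$outcome) == 1L
  v <- values[cases]
  md <- metadata[cases, , drop = FALSE]
  contrast <- function(name, g1, g2) {
    n1 <- sum(g1, na.rm = TRUE); n2 <- sum(g2, na.rm = TRUE)
    if (n1 < 2L || n2 < 2L) {
      return(data.frame(contrast = name, n1 = n1, n2 = n2, p = NA_real_,
                        skipped = TRUE, underpowered = TRUE,
                        stringsAsFactors = FALSE))
    }
    data.frame(contrast = name, n1 = n1, n2 = n2,
               p = mann_whitney_p(v[which(g1)], v[which(g2)]),
               skipped = FALSE, underpowered = n1 < min_n || n2 < min_n,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    contrast("early_vs_late_onset", md$onset == "early", md$onset == "late"),
    contrast("mild_vs_severe_pe", md$pe_severity == "mild",
             md$pe_severity == "severe"),
    contrast("gh_vs_pe_hellp", md$hdp_subtype == "GH",
             md$hdp_subtype %in% c("PE", "HELLP")))
  rownames(out) <- NULL
  out
}

#' Rank correlation of persistent features with CVD risk factors
#'
#' Spearman correlation of each feature against each risk factor (BMI,
#' systolic and diastolic blood pressure by default) with two-sided p.
#' Constant vectors yield an undefined correlation, reported as NA.
#'
#' @param features feature table or numeric matrix (columns = features).
#' @param risk_factors data.frame of numeric risk factors.
#' @return data.frame: `feature`, `risk_factor`, `rho`, `p`, `n`.
#' @export
riskfactor_correlation <- function(features, risk_factors) {
  x <- feature_matrix(features)
  rf <- as.data.frame(risk_factors)
  rows <- list()
  for (j in colnames(x)) {
    for (v in names(rf)) {
      a <- x[, j]; b <- rf[[v]]
      ok <- stats::complete.cases(a, b)
      n <- sum(ok)
      if (n < 3L) stop("need >= 3 paired observations", call. = FALSE)
      if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
        rows[[paste(j, v)]] <- data.frame(feature = j, risk_factor = v,
                                          rho = NA_real_, p = NA_real_,
                                          n = n, stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(a[ok], b[ok],
                                             method = "spearman"))
      rows[[paste(j, v)]] <- data.frame(feature = j, risk_factor = v,
                                        rho = unname(ct$estimate),
                                        p = ct$p.value, n = n,
                                        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
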
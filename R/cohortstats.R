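# Demographic comparisons: Welch t-tests from summary statistics, two-sided
# Fisher exact tests, and assembly of a cohort demographics table from raw
# metadata or from published summaries.

#' Group summary for a variance-based test
#'
#' @param mean,sd,n group mean, standard deviation (>= 0) and size (>= 2).
#' @return a `group_summary` list.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  n <- stopifnot_scalar_count(n, "n")
  if (n < 2L) stop("n must be >= 2 for a variance-based test", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = n), class = "group_summary")
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' computed from group means, SDs and sizes only. Degenerate case: if both
#' SDs are zero the p-value is 1 for equal means and 0 (flagged) otherwise.
#'
#' @param g1,g2 `group_summary` objects (or lists with mean/sd/n).
#' @return list with `t`, `df`, `p` (two-sided) and `degenerate` flag.
#' @export
#' @examples
#' welch_t_from_summary(group_summary(32.54, 6.94, 28),
#'                      group_summary(26.50, 3.56, 38))
welch_t_from_summary <- function(g1, g2) {
  if (g1$sd == 0 && g2$sd == 0) {
    equal <- isTRUE(all.equal(g1$mean, g2$mean))
    return(list(t = if (equal) 0 else Inf * sign(g1$mean - g2$mean),
                df = NA_real_, p = if (equal) 1 else 0, degenerate = TRUE))
  }
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  tval <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       degenerate = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric point probabilities not
#' exceeding that of the observed table (relative tolerance 1e-7), via
#' [stats::fisher.test()].
#'
#' @param a,b,c,d cases-with, cases-without, controls-with, controls-without.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(8, 34, 0, 37)   # ~0.006
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    # a zero margin leaves a single admissible table
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Published demographic summaries of the three study cohorts
#'
#' Mean (SD) per arm for the continuous demographics and event counts for the
#' binary ones, for the antepartum (AP, 28 cases / 38 controls), postpartum
#' (PP, 42/37) and midlife (ML, 70/74) hypertensive-disorders-of-pregnancy
#' case/control cohorts. These printed summaries are the inputs to the
#' summary-statistics tests and the defaults of the synthetic confounder
#' generator. `visit_timing` is gestational weeks (AP), weeks postpartum
#' (PP), or years since delivery (ML). Midlife case rows with one missing
#' value are encoded with n = 69.
#'
#' @return data.frame with columns `variable`, `type` ("continuous" or
#'   "binary"), `cohort`, `arm`, `mean`, `sd`, `count`, `n`.
#' @export
hdp_cohort_summaries <- function() {
  cont <- function(variable, cohort, arm, mean, sd, n) {
    data.frame(variable = variable, type = "continuous", cohort = cohort,
               arm = arm, mean = mean, sd = sd, count = NA_integer_, n = n,
               stringsAsFactors = FALSE)
  }
  bin <- function(variable, cohort, arm, count, n) {
    data.frame(variable = variable, type = "binary", cohort = cohort,
               arm = arm, mean = NA_real_, sd = NA_real_, count = count,
               n = n, stringsAsFactors = FALSE)
  }
  rbind(
    cont("age", "AP", "case", 33.86, 5.18, 28),
    cont("age", "AP", "control", 32.95, 4.45, 38),
    cont("age", "PP", "case", 34.10, 4.38, 42),
    cont("age", "PP", "control", 33.51, 3.47, 37),
    cont("age", "ML", "case", 40.20, 6.35, 70),
    cont("age", "ML", "control", 40.89, 5.27, 74),
    cont("parity", "AP", "case", 0.79, 1.17, 28),
    cont("parity", "AP", "control", 0.42, 0.55, 38),
    cont("parity", "PP", "case", 1.67, 1.07, 42),
    cont("parity", "PP", "control", 1.38, 0.55, 37),
    cont("parity", "ML", "case", 2.07, 1.20, 69),
    cont("parity", "ML", "control", 1.97, 0.86, 74),
    cont("bmi", "AP", "case", 32.54, 6.94, 28),
    cont("bmi", "AP", "control", 26.50, 3.56, 38),
    cont("bmi", "PP", "case", 28.46, 6.54, 42),
    cont("bmi", "PP", "control", 24.65, 3.47, 37),
    cont("bmi", "ML", "case", 26.50, 4.98, 69),
    cont("bmi", "ML", "control", 24.17, 4.90, 74),
    cont("visit_timing", "AP", "case", 33.32, 3.40, 28),
    cont("visit_timing", "AP", "control", 33.50, 3.52, 38),
    cont("visit_timing", "PP", "case", 16.81, 12.30, 42),
    cont("visit_timing", "PP", "control", 9.61, 5.65, 37),
    cont("visit_timing", "ML", "case", 5.87, 3.44, 70),
    cont("visit_timing", "ML", "control", 5.87, 3.83, 74),
    cont("systolic_bp", "AP", "case", 129.48, 14.75, 28),
    cont("systolic_bp", "AP", "control", 103.01, 15.86, 38),
    cont("systolic_bp", "PP", "case", 114.52, 9.46, 42),
    cont("systolic_bp", "PP", "control", 105.69, 8.01, 37),
    cont("systolic_bp", "ML", "case", 118.41, 10.76, 69),
    cont("systolic_bp", "ML", "control", 111.43, 11.30, 74),
    cont("diastolic_bp", "AP", "case", 78.37, 8.39, 28),
    cont("diastolic_bp", "AP", "control", 64.22, 6.97, 38),
    cont("diastolic_bp", "PP", "case", 73.01, 7.42, 42),
    cont("diastolic_bp", "PP", "control", 67.86, 6.16, 37),
    cont("diastolic_bp", "ML", "case", 75.14, 8.52, 69),
    cont("diastolic_bp", "ML", "control", 70.11, 9.12, 74),
    bin("gestational_diabetes", "AP", "case", 6L, 28),
    bin("gestational_diabetes", "AP", "control", 0L, 38),
    bin("gestational_diabetes", "PP", "case", 8L, 42),
    bin("gestational_diabetes", "PP", "control", 0L, 37),
    bin("gestational_diabetes", "ML", "case", 6L, 70),
    bin("gestational_diabetes", "ML", "control", 0L, 74),
    bin("nulli_primiparous", "AP", "case", 17L, 28),
    bin("nulli_primiparous", "AP", "control", 23L, 38),
    bin("nulli_primiparous", "PP", "case", 26L, 42),
    bin("nulli_primiparous", "PP", "control", 24L, 37),
    bin("nulli_primiparous", "ML", "case", 0L, 69),
    bin("nulli_primiparous", "ML", "control", 0L, 74)
  )
}

#' Cohort demographic comparison table from summary statistics
#'
#' For every (variable, cohort) pair runs the Welch t-test on the printed
#' mean/SD/n (continuous variables) or the two-sided Fisher exact test on the
#' counts (binary variables), recomputing percentages from counts.
#'
#' @param summaries a data.frame in the [hdp_cohort_summaries()] layout.
#' @return data.frame with one row per variable x cohort: per-arm summaries
#'   and the test p-value (`test` = "welch" or "fisher").
#' @export
build_table2_from_summaries <- function(summaries = hdp_cohort_summaries()) {
  keys <- unique(summaries[, c("variable", "cohort")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    v <- keys$variable[i]; co <- keys$cohort[i]
    s <- summaries[summaries$variable == v & summaries$cohort == co, ]
    ca <- s[s$arm == "case", ]; ct <- s[s$arm == "control", ]
    if (nrow(ca) != 1L || nrow(ct) != 1L) {
      stop("cohort ", co, " needs one case and one control row for ", v,
           call. = FALSE)
    }
    if (ca$type == "continuous") {
      res <- welch_t_from_summary(group_summary(ca$mean, ca$sd, ca$n),
                                  group_summary(ct$mean, ct$sd, ct$n))
      data.frame(variable = v, cohort = co, test = "welch",
                 case_mean = ca$mean, case_sd = ca$sd, case_n = ca$n,
                 control_mean = ct$mean, control_sd = ct$sd, control_n = ct$n,
                 case_pct = NA_real_, control_pct = NA_real_,
                 statistic = res$t, p = res$p, stringsAsFactors = FALSE)
    } else {
      p <- fisher_exact_2x2(ca$count, ca$n - ca$count,
                            ct$count, ct$n - ct$count)
      data.frame(variable = v, cohort = co, test = "fisher",
                 case_mean = NA_real_, case_sd = NA_real_, case_n = ca$n,
                 control_mean = NA_real_, control_sd = NA_real_,
                 control_n = ct$n,
                 case_pct = 100 * ca$count / ca$n,
                 control_pct = 100 * ct$count / ct$n,
                 statistic = NA_real_, p = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort demographic comparison table from raw metadata
#'
#' Summarizes each demographic variable per arm within each cohort and tests
#' case/control differences (Welch t for numeric, Fisher exact for binary).
#' Missing values are excluded per variable with the effective n reported.
#'
#' @param metadata data.frame with columns `cohort`, `outcome`
#'   (case/control or 0/1) and the demographic variables.
#' @param continuous,binary character vectors naming variable columns.
#' @return data.frame in the [build_table2_from_summaries()] layout.
#' @export
build_table2 <- function(metadata,
                         continuous = c("age", "parity", "bmi",
                                        "visit_timing", "systolic_bp",
                                        "diastolic_bp"),
                         binary = "gestational_diabetes") {
  y <- as_binary_outcome(metadata$outcome)
  rows <- list()
  for (co in unique(as.character(metadata$cohort))) {
    in_cohort <- metadata$cohort == co
    if (length(unique(y[in_cohort])) < 2L) {
      stop("cohort ", co, " has a single arm", call. = FALSE)
    }
    for (v in c(continuous, binary)) {
      if (!v %in% names(metadata)) next
      vals <- metadata[[v]][in_cohort]
      arm <- y[in_cohort]
      ok <- !is.na(vals)
      vals <- vals[ok]; arm <- arm[ok]
      if (v %in% continuous) {
        ca <- vals[arm == 1L]; ct <- vals[arm == 0L]
        res <- welch_t_from_summary(
          group_summary(mean(ca), stats::sd(ca), length(ca)),
          group_summary(mean(ct), stats::sd(ct), length(ct)))
        rows[[paste(co, v)]] <- data.frame(
          variable = v, cohort = co, test = "welch",
          case_mean = mean(ca), case_sd = stats::sd(ca), case_n = length(ca),
          control_mean = mean(ct), control_sd = stats::sd(ct),
          control_n = length(ct),
          case_pct = NA_real_, control_pct = NA_real_,
          statistic = res$t, p = res$p, stringsAsFactors = FALSE)
      } else {
        a <- sum(vals[arm == 1L] != 0); n1 <- sum(arm == 1L)
        c_ <- sum(vals[arm == 0L] != 0); n0 <- sum(arm == 0L)
        rows[[paste(co, v)]] <- data.frame(
          variable = v, cohort = co, test = "fisher",
          case_mean = NA_real_, case_sd = NA_real_, case_n = n1,
          control_mean = NA_real_, control_sd = NA_real_, control_n = n0,
          case_pct = 100 * a / n1, control_pct = 100 * c_ / n0,
          statistic = NA_real_,
          p = fisher_exact_2x2(a, n1 - a, c_, n0 - c_),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
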
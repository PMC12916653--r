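# Downstream analyses: screens, Venn persistence, confounder adjustment,
# subtype stratification, risk-factor correlation.

test_that("the univariate screen is calibrated under the null", {
  rates <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(40 * 1000), nrow = 40,
                dimnames = list(NULL, paste0("f", 1:1000)))
    y <- rep(c(0L, 1L), each = 20)
    mean(univariate_screen(x, y)$significant)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("screen p-values equal mann_whitney_p and flag extremes", {
  set.seed(4)
  x <- cbind(a = rnorm(40), b = c(rnorm(20), rnorm(20) + 50), cst = rep(1, 40))
  y <- rep(c(0L, 1L), each = 20)
  sc <- univariate_screen(x, y)
  expect_identical(sc$p[sc$feature == "a"],
                   mann_whitney_p(x[y == 1, "a"], x[y == 0, "a"]))
  # disjoint supports at n = 20 + 20
  expect_lt(sc$p[sc$feature == "b"], 1e-6)
  expect_equal(sc$direction[sc$feature == "b"], 1L)
  # constant feature: p = 1, direction 0, never significant
  expect_equal(sc$p[sc$feature == "cst"], 1)
  expect_equal(sc$direction[sc$feature == "cst"], 0L)
  expect_false(sc$significant[sc$feature == "cst"])
})

# brute-force region oracle over explicit membership enumeration
venn_oracle <- function(sets, vocab) {
  out <- integer(0)
  cohorts <- names(sets)
  for (k in seq_along(cohorts)) {
    for (combo in as.data.frame(combn(cohorts, k), stringsAsFactors = FALSE)) {
      inside <- vapply(vocab, function(f) {
        all(vapply(combo, function(co) f %in% sets[[co]], logical(1))) &&
          !any(vapply(setdiff(cohorts, combo), function(co) {
            f %in% sets[[co]]
          }, logical(1)))
      }, logical(1))
      out[paste(combo, collapse = "&")] <- sum(inside)
    }
  }
  out
}

fake_screen <- function(vocab, sig, direction = 1L) {
  data.frame(feature = vocab, p = ifelse(vocab %in% sig, 0.01, 0.8),
             q = NA_real_, direction = direction,
             significant = vocab %in% sig, stringsAsFactors = FALSE)
}

test_that("venn region counts match the brute-force oracle", {
  vocab <- letters[1:8]
  sets <- list(AP = c("a", "b", "c"), PP = c("b", "c", "d"), ML = c("c", "e"))
  screens <- lapply(sets, function(s) fake_screen(vocab, s))
  rep3 <- persistence_venn(screens)
  oracle <- venn_oracle(sets, vocab)
  expect_equal(rep3$region_counts[names(oracle)], oracle)
  expect_equal(rep3$shared$feature, "c")
  expect_equal(sum(rep3$region_counts), length(unique(unlist(sets))))
  # disjoint sets: all intersection regions empty
  disjoint <- lapply(list(AP = "a", PP = "b", ML = "c"), function(s) {
    fake_screen(vocab, s)
  })
  repd <- persistence_venn(disjoint)
  expect_true(all(repd$region_counts[grepl("&", names(repd$region_counts))] ==
                    0))
  # cohort order permutation only relabels regions (region keys follow the
  # supplied cohort order)
  perm <- persistence_venn(screens[c("ML", "AP", "PP")])
  expect_equal(unname(perm$region_counts[c("AP", "AP&PP", "ML&AP&PP")]),
               unname(rep3$region_counts[c("AP", "AP&PP", "AP&PP&ML")]))
  expect_equal(sum(perm$region_counts), sum(rep3$region_counts))
  expect_error(persistence_venn(list(AP = fake_screen(vocab, "a"),
                                     PP = fake_screen(letters[2:9], "b"))),
               "mismatched")
})

test_that("direction consistency of shared features is tracked", {
  vocab <- c("up", "down", "flip")
  s1 <- fake_screen(vocab, vocab, direction = c(1L, -1L, 1L))
  s2 <- fake_screen(vocab, vocab, direction = c(1L, -1L, -1L))
  rep2 <- persistence_venn(list(A = s1, B = s2))
  expect_equal(rep2$shared$consistent, c(TRUE, TRUE, FALSE))
})

test_that("persistently planted features land in the triple intersection", {
  pe <- rbind(planted_effect("freq", "Bcells", "frequency", 1.5),
              planted_effect("IL246", "CD4T_naive", "pSTAT3", -1.5))
  ids <- planted_ids(pe)
  hits <- vapply(1:10, function(seed) {
    screens <- lapply(c(AP = 1, PP = 2, ML = 3), function(k) {
      g <- make_cohort(seed * 100 + k, n_cases = 40, n_controls = 40,
                       planted = pe)
      univariate_screen(g$features, g$y)
    })
    all(ids %in% persistence_venn(screens)$shared$feature)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("confounder adjustment reduces to the plain LRT with no confounders", {
  set.seed(8)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  pred <- plogis(qlogis(0.5) + y * 1 + rnorm(n, sd = 1))
  res <- confounder_adjustment(pred, y, data.frame()[seq_len(n), , drop = FALSE])
  ref <- anova(glm(y ~ 1, family = "binomial"),
               glm(y ~ pred, family = "binomial"), test = "LRT")
  expect_equal(res$prediction_p, ref[["Pr(>Chi)"]][2], tolerance = 1e-9)
  expect_true(res$still_predictive)
})

test_that("an independent confounder does not explain the predictions", {
  ps <- vapply(1:100, function(seed) {
    set.seed(seed)
    n <- 80
    y <- rep(c(0L, 1L), each = n / 2)
    pred <- plogis(y - 0.5 + rnorm(n))
    bmi <- rnorm(n, 27, 5)
    confounder_adjustment(pred, y, data.frame(bmi = bmi))$terms$p[
      confounder_adjustment(pred, y,
                            data.frame(bmi = bmi))$terms$term == "bmi"]
  }, numeric(1))
  # null p-values should be uniform
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("full confounding removes the prediction term's significance", {
  flags <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 100
    bmi <- rnorm(n, 27, 5)
    y <- rbinom(n, 1, plogis((bmi - 27) / 2.5))
    pred <- plogis((bmi - 27) / 2.5)   # prediction is a function of BMI only
    res <- confounder_adjustment(pred, y, data.frame(bmi = bmi))
    res$prediction_p > 0.05
  }, logical(1))
  expect_gte(mean(flags), 0.8)
})

test_that("missing confounders are dropped with a reported count", {
  set.seed(12)
  n <- 60
  y <- rep(c(0L, 1L), each = 30)
  pred <- plogis(y - 0.5 + rnorm(n))
  conf <- data.frame(bmi = rnorm(n, 27, 5))
  conf$bmi[1:3] <- NA
  expect_message(res <- confounder_adjustment(pred, y, conf), "3 sample")
  expect_equal(res$n_dropped, 3)
})

test_that("subtype contrasts skip tiny levels and detect planted shifts", {
  cfg <- synthetic_config("PP", seed = 31)
  md <- generate_confounders(cfg)
  set.seed(31)
  v <- rnorm(nrow(md))
  null_res <- subtype_stratify(v, md)
  expect_true(all(!null_res$skipped))
  # single-member level forces a skip with a flag
  md2 <- md
  cases <- which(md2$outcome == "case")
  md2$onset[cases] <- "late"
  md2$onset[cases[1]] <- "early"
  res2 <- subtype_stratify(v, md2)
  row <- res2[res2$contrast == "early_vs_late_onset", ]
  expect_true(row$skipped)
  expect_true(row$underpowered)

  # planted onset shift of 1.5 SD at 15 vs 15 cases
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    md3 <- md[md$outcome == "case", ][1:30, ]
    md3$onset <- rep(c("early", "late"), each = 15)
    vv <- rnorm(30) + ifelse(md3$onset == "early", 1.5, 0)
    res <- subtype_stratify(vv, md3)
    res$p[res$contrast == "early_vs_late_onset"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # identical subtype distributions rarely reach significance
  nulls <- vapply(1:10, function(seed) {
    set.seed(100 + seed)
    vv <- rnorm(nrow(md))
    res <- subtype_stratify(vv, md)
    all(res$p[!res$skipped] > 0.05)
  }, logical(1))
  expect_gte(mean(nulls), 0.7)
})

test_that("risk-factor correlation recovers identity and independence", {
  set.seed(5)
  bmi <- rnorm(100, 27, 5)
  x <- cbind(self = bmi, indep = rnorm(100))
  res <- riskfactor_correlation(x, data.frame(bmi = bmi))
  expect_equal(res$rho[res$feature == "self"], 1.0)
  null_rho <- vapply(1:10, function(seed) {
    set.seed(seed)
    r <- riskfactor_correlation(cbind(f = rnorm(100)),
                                data.frame(bmi = rnorm(100, 27, 5)))
    abs(r$rho)
  }, numeric(1))
  expect_gte(mean(null_rho < 0.2), 0.9)
  # constant vector: correlation undefined, reported NA
  resc <- riskfactor_correlation(cbind(cst = rep(1, 100)),
                                 data.frame(bmi = bmi))
  expect_true(is.na(resc$rho))
  expect_error(riskfactor_correlation(cbind(f = 1:2),
                                      data.frame(bmi = c(1, 2))),
               ">= 3")
})

test_that("spearman matches the brute-force rank formula on a worked set", {
  x <- c(3, 1, 4, 1.5, 5)
  y <- c(2, 1, 3, 2.5, 4.5)
  # no ties: rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))
  d <- rank(x) - rank(y)
  rho_manual <- 1 - 6 * sum(d^2) / (5 * 24)
  res <- riskfactor_correlation(cbind(f = x), data.frame(v = y))
  expect_equal(res$rho, rho_manual, tolerance = 1e-12)
})
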
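# Feature derivation: arcsinh transform, frequencies, signaling responses,
# penalization.

test_that("arcsinh transform matches closed forms and is odd", {
  expect_equal(arcsinh_transform(0), 0)
  expect_equal(arcsinh_transform(5, 5), log(1 + sqrt(2)))
  expect_equal(arcsinh_transform(5, 5), 0.881374, tolerance = 1e-6)
  expect_equal(arcsinh_transform(-5, 5), -arcsinh_transform(5, 5))
  expect_error(arcsinh_transform(1, 0), "positive")
})

# a tiny hand-built event table: counts are exact so frequencies are exact
tiny_events <- function() {
  mk <- function(sample, condition, type, n, value = 10) {
    data.frame(sample_id = sample, condition = condition, cell_type = type,
               m1 = rep(value, n), stringsAsFactors = FALSE)
  }
  rbind(mk("s1", "Unstim", "Bcells", 20), mk("s1", "Unstim", "cMC", 180),
        mk("s1", "LPS", "Bcells", 20), mk("s1", "LPS", "cMC", 180))
}

tiny_config <- function() {
  feature_derivation_config(mononuclear_types = c("Bcells", "cMC"),
                            granulocyte_types = "Neutrophils",
                            conditions = c("Unstim", "LPS"))
}

test_that("cell frequencies are exact percentages with both denominators", {
  f <- cell_frequencies(tiny_events(), tiny_config())
  expect_equal(f[["freq|Bcells|frequency"]], 10)     # 20 of 200 mononuclear
  expect_equal(f[["freq|cMC|frequency"]], 90)
  expect_equal(f[["freq|Neutrophils|frequency"]], 0) # no granulocyte events
  # leaf mononuclear populations partition the mononuclear events
  expect_equal(f[["freq|Bcells|frequency"]] + f[["freq|cMC|frequency"]], 100)
})

test_that("granulocyte frequencies use the singlet-leukocyte denominator", {
  ev <- rbind(tiny_events(),
              data.frame(sample_id = "s1", condition = "Unstim",
                         cell_type = "Neutrophils", m1 = rep(10, 300),
                         stringsAsFactors = FALSE))
  f <- cell_frequencies(ev, tiny_config())
  expect_equal(f[["freq|Neutrophils|frequency"]], 100 * 300 / 500)
  # mononuclear percentages are unaffected by granulocyte events
  expect_equal(f[["freq|Bcells|frequency"]], 10)
})

test_that("zero mononuclear events is an error naming the sample", {
  ev <- data.frame(sample_id = "s9", condition = "Unstim",
                   cell_type = "Neutrophils", m1 = rep(1, 10),
                   stringsAsFactors = FALSE)
  expect_error(cell_frequencies(ev, tiny_config()), "s9")
})

test_that("signaling features match closed-form arcsinh differences", {
  ev <- tiny_events()
  f0 <- signaling_features(ev, tiny_config())
  expect_equal(f0[["LPS|Bcells|m1"]], 0)  # identical stim and unstim
  # unstim median 5, stim median 12.42: asinh(2.484) - asinh(1)
  ev2 <- ev
  ev2$m1[ev2$condition == "Unstim"] <- 5
  ev2$m1[ev2$condition == "LPS"] <- 12.42
  f2 <- signaling_features(ev2, tiny_config())
  expect_equal(f2[["LPS|cMC|m1"]], asinh(12.42 / 5) - asinh(1),
               tolerance = 1e-12)
  expect_equal(f2[["LPS|cMC|m1"]], 0.7599, tolerance = 1e-4)
  expect_equal(f2[["Unstim|cMC|m1"]], asinh(1))
})

test_that("a multiplicative shift at high intensity recovers log k", {
  k <- 3.7
  ev <- tiny_events()
  ev$m1[ev$condition == "Unstim"] <- 5000
  ev$m1[ev$condition == "LPS"] <- 5000 * k
  f <- signaling_features(ev, tiny_config())
  expect_equal(f[["LPS|cMC|m1"]], log(k), tolerance = 1e-5)
})

test_that("derived features are invariant to event row order", {
  cfg <- event_config(seed = 21, n_cases = 3, n_controls = 3)
  ev <- generate_events(cfg)$events
  fc <- event_derivation_config(cfg)
  f1 <- derive_features(ev, fc)
  set.seed(1)
  f2 <- derive_features(ev[sample.int(nrow(ev)), ], fc)
  expect_equal(f1, f2)
})

test_that("raising one group's intensities weakly raises its endogenous feature", {
  cfg <- event_config(seed = 22, n_cases = 2, n_controls = 2)
  ev <- generate_events(cfg)$events
  fc <- event_derivation_config(cfg)
  base <- signaling_features(ev, fc)
  ev2 <- ev
  hit <- ev2$sample_id == ev2$sample_id[1] & ev2$cell_type == "cMC" &
    ev2$condition == "Unstim"
  ev2$pCREB[hit] <- ev2$pCREB[hit] * 2
  up <- signaling_features(ev2, fc)
  i <- which(base$sample_id == ev$sample_id[1])
  expect_gt(up[["Unstim|cMC|pCREB"]][i], base[["Unstim|cMC|pCREB"]][i])
  # other samples untouched
  expect_equal(up[["Unstim|cMC|pCREB"]][-i], base[["Unstim|cMC|pCREB"]][-i])
})

test_that("too few cells for a median is an error listing offending keys", {
  ev <- tiny_events()
  ev <- rbind(ev, data.frame(sample_id = "s1", condition = "Unstim",
                             cell_type = "Neutrophils", m1 = c(1, 2),
                             stringsAsFactors = FALSE))
  expect_error(signaling_features(ev, tiny_config()),
               "Neutrophils.*Unstim.*2 cells")
})

test_that("penalization mask arithmetic assembles the canonical feature space", {
  mask <- build_penalization_mask()
  sizes <- mask_strata_sizes(mask)
  expect_equal(unname(sizes[c("freq", "Unstim", "LPS", "IL246", "IL18")]),
               c(35, 700, 248, 635, 554))
  expect_equal(unname(sizes["total"]), 2172)
  expect_equal(length(mask_feature_ids(mask)), 2172)
})

test_that("apply_penalization keeps, drops and reports columns correctly", {
  cfg <- event_config(seed = 23, n_cases = 2, n_controls = 2)
  ev <- generate_events(cfg)$events
  fc <- event_derivation_config(cfg)
  full <- derive_features(ev, fc)
  mask <- build_penalization_mask(cfg$cell_types, cfg$markers,
                                  strata_sizes = c(LPS = 32, IL246 = 32,
                                                   IL18 = 32))
  # all-ones mask: identity
  ones <- mask
  ones$include <- 1L
  kept <- apply_penalization(full, ones)
  expect_equal(names(kept), names(full))
  # excluding exactly one feature drops exactly that column
  one_out <- ones
  i <- which(one_out$condition == "LPS" & one_out$cell_type == "cMC" &
               one_out$marker == "pCREB")
  one_out$include[i] <- 0L
  dropped <- apply_penalization(full, one_out)
  expect_equal(ncol(dropped), ncol(full) - 1L)
  expect_false("LPS|cMC|pCREB" %in% names(dropped))
  # strata sizes reported
  sub <- apply_penalization(full, mask)
  expect_equal(unname(attr(sub, "strata_sizes")[c("LPS", "IL246", "IL18")]),
               c(32, 32, 32))
  # invalid mask values and missing coverage are errors
  bad <- ones; bad$include[1] <- 2L
  expect_error(apply_penalization(full, bad), "0 or 1")
  expect_error(apply_penalization(full, ones[-1, ]), "does not cover")
})

test_that("mask CSV round trip preserves the mask", {
  mask <- build_penalization_mask(
    cell_types = c("cMC", "Bcells", "Neutrophils"),
    markers = c("pCREB", "pSTAT3"),
    strata_sizes = c(LPS = 3, IL246 = 4, IL18 = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_penalization_mask(mask, path)
  back <- read_penalization_mask(path)
  expect_equal(as.data.frame(back), as.data.frame(mask))
})

test_that("event-derived responses recover the configured stimulation shift", {
  # high baseline puts medians in the log regime, so the arcsinh response
  # approximates the multiplicative shift log(2.5)
  cfg <- event_config(seed = 31, n_cases = 10, n_controls = 10,
                      baseline_location = log(500))
  ev <- generate_events(cfg)
  f <- derive_features(ev$events, event_derivation_config(cfg))
  resp <- mean(f[["LPS|cMC|pCREB"]])
  expect_lt(abs(resp - log(2.5)), 0.15)
  # non-targeted population stays near zero
  expect_lt(abs(mean(f[["LPS|Bcells|pCREB"]])), 0.15)
})
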
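# Fixtures shared across the suite: a compact 200-feature space for model
# tests and a small event-level vocabulary for feature-derivation tests.

small_strata <- c(freq = 20, Unstim = 60, LPS = 40, IL246 = 40, IL18 = 40)

# ten planted signaling/frequency effects inside the compact feature space
planted_ten <- function(effect = 2) {
  rbind(
    planted_effect("Unstim", "cMC", "pSTAT3", effect),
    planted_effect("Unstim", "ncMC", "pCREB", effect),
    planted_effect("Unstim", "intMC", "pS6", effect),
    planted_effect("LPS", "cMC", "pNFkB", effect),
    planted_effect("LPS", "intMC", "pCREB", effect),
    planted_effect("IL246", "CD4T_naive", "pSTAT3", -effect),
    planted_effect("IL246", "Th1", "pSTAT5", effect),
    planted_effect("IL18", "NK_CD56dim", "pCREB", effect),
    planted_effect("IL18", "NK_CD56bright", "pNFkB", effect),
    planted_effect("freq", "Bcells", "frequency", effect)
  )
}

planted_ids <- function(pe) make_feature_id(pe$stratum, pe$cell_type, pe$marker)

make_cohort <- function(seed, n_cases = 30, n_controls = 30,
                        planted = NULL, cohort = "AP",
                        strata_sizes = small_strata) {
  cfg <- synthetic_config(cohort, n_cases = n_cases,
                          n_controls = n_controls,
                          strata_sizes = strata_sizes,
                          planted_effects = planted, seed = seed)
  g <- generate_feature_table(cfg)
  g$y <- as.integer(g$metadata$outcome == "case")
  g
}

# compact vocabulary for event-level simulation (keeps every population
# abundant enough for stable medians at a few hundred cells per aliquot)
event_config <- function(seed, n_cases = 8, n_controls = 8,
                         cells_per_sample = 300, ...) {
  synthetic_config(
    "AP", n_cases = n_cases, n_controls = n_controls,
    cell_types = c("cMC", "CD4T_cm", "NK_CD56dim", "Bcells", "CD4T_naive",
                   "CD8T_naive", "Neutrophils", "Eosinophils"),
    markers = c("pCREB", "pSTAT3", "pNFkB", "CXCR4"),
    cells_per_sample = cells_per_sample, seed = seed, ...)
}

event_derivation_config <- function(cfg, ...) {
  feature_derivation_config(
    mononuclear_types = setdiff(cfg$cell_types, cfg$granulocyte_types),
    granulocyte_types = intersect(cfg$cell_types,
                                  default_granulocyte_types()),
    ...)
}
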
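# persimmune

Immune feature derivation and sparse case/control modeling for
mass-cytometry (CyTOF) immunome studies of hypertensive disorders of
pregnancy (HDP).

## The problem

Women whose pregnancies are complicated by preeclampsia or gestational
hypertension carry an elevated long-term risk of cardiovascular disease,
and persistent immune dysregulation is a candidate mechanism. Studying it
requires profiling the distribution and functional state of the major
peripheral immune cell subsets — the immunome — in case/control cohorts
sampled during pregnancy (antepartum, AP), after delivery (postpartum, PP)
and years later (midlife, ML), then asking whether sparse multivariable
immune signatures discriminate cases from controls at each timepoint,
whether they transfer across timepoints, and which individual features stay
dysregulated throughout.

`persimmune` implements that analysis pipeline end to end for stimulated
whole-blood mass-cytometry data (unstimulated, LPS, IL-2/IL-4/IL-6 and
IL-18 conditions), together with a seeded synthetic-data generator so every
stage is testable without patient data.

## What it computes

**Features.** From gated per-cell event tables, each sample yields:

* cell frequencies — mononuclear subsets as % of mononuclear cells,
  granulocyte subsets as % of singlet leukocytes;
* endogenous signaling — `asinh(median intensity / 5)` per
  (cell type, marker) in the unstimulated aliquot;
* stimulation responses — the difference in arcsinh-transformed median
  intensity between a stimulated and the unstimulated aliquot.

A binary prior-knowledge **penalization matrix** over
(cell type × marker × condition) restricts responses to combinations
supported by canonical receptor-to-pathway knowledge (e.g. LPS/TLR4/MyD88
signaling is myeloid-restricted). At the default per-stratum sizes the
five strata (35 frequencies, 700 endogenous, 248 LPS, 635 IL-2/IL-4/IL-6,
554 IL-18) assemble to 2,172 features per sample.

**Models.** Sparse logistic classifiers over the feature table: lasso,
adaptive lasso, and their stability-selected counterparts (permutation
decoys calibrate a selection-frequency threshold through a
false-discovery-proportion proxy), with early fusion (one model over all
strata) or late fusion (per-stratum models combined by a logistic stacker
on out-of-fold probabilities).

**Evaluation.** Repeated stratified 5-fold cross-validation (study setting:
200 repeats); pooled out-of-fold AUROC per repeat, summarized as the median
with a 2.5–97.5% quantile interval; significance by the two-sided
Mann–Whitney U test on per-sample median out-of-fold probabilities
(AUROC = U / n₁n₀); cross-timepoint transfer of a trained model without
refitting.

**Downstream.** Univariate Mann–Whitney screens per cohort with Venn
overlap of significant features across cohorts (persistence analysis);
confounder adjustment via `outcome ~ prediction + confounders` with
drop-one likelihood-ratio tests (plus a linear-model F-test variant);
HDP-subtype stratification; Spearman correlation of persistent features
with CVD risk factors; and Welch-t / Fisher-exact cohort demographic
comparisons computable from printed summary statistics alone.

## Worked example

```r
library(persimmune)

# a synthetic antepartum-style cohort with two planted case effects:
# raised B-cell frequency, depressed pSTAT3 response to IL-2/IL-4/IL-6
pe <- rbind(planted_effect("freq",  "Bcells",     "frequency", 2),
            planted_effect("IL246", "CD4T_naive", "pSTAT3",   -2))
cfg <- synthetic_config("AP", n_cases = 30, n_controls = 30,
                        strata_sizes = c(freq = 20, Unstim = 60, LPS = 40,
                                         IL246 = 40, IL18 = 40),
                        planted_effects = pe, seed = 1)
g <- generate_feature_table(cfg)

report <- repeated_cv(g$features, g$metadata$outcome,
                      model_spec("lasso", seed = 1),
                      cv_config(n_repeats = 20, seed = 1))
report
#> Cross-validated lasso (early fusion)
#>   AUROC (median of 20 repeats): 0.872 [0.825, 0.903]
#>   Mann-Whitney p: 6.53e-07 (significant)
#>   Selected features: 5
```

The median cross-validated AUROC (0.872) is the headline discrimination
estimate, the bracket is the quantile interval across the 20 repeats, the
Mann–Whitney p compares cases' and controls' aggregated out-of-fold
probabilities, and the selected features are the nonzero coefficients of
the final whole-data fit — here both planted effects plus correlated
neighbors from the same feature block:

```r
selected_features(report$final_fit)
#> [1] "freq|Bcells|frequency"   "IL246|Tfh|pSTAT1"
#> [3] "IL246|Tfh|pSTAT3"        "IL246|Tfh|pSTAT5"
#> [5] "IL246|CD4T_naive|pSTAT3"
```

Demographic comparisons recompute directly from published summary
statistics:

```r
welch_t_from_summary(group_summary(32.54, 6.94, 28),   # case BMI
                     group_summary(26.50, 3.56, 38))$p # control BMI
#> 0.0001515641
fisher_exact_2x2(8, 34, 0, 37)   # gestational diabetes, 8/42 vs 0/37
#> 0.006004044
```

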
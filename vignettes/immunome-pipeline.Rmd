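---
title: "Methods: the persimmune immunome analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the persimmune immunome analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persimmune)
```

`persimmune` analyzes stimulated whole-blood mass-cytometry immune
profiles of hypertensive-disorders-of-pregnancy (HDP) case/control cohorts.
This vignette documents the model and procedure behind each stage, the
parameters that matter, the numerical choices, and the limits of what the
synthetic-data tests demonstrate.

## Feature derivation

Each participant contributes four aliquots — unstimulated (PBS), LPS,
an IL-2/IL-4/IL-6 cocktail, and IL-18 — acquired after a short ex vivo
stimulation, with cells pre-labeled by a gating hierarchy into 35
populations (33 mononuclear, 2 granulocyte). Three feature families are
derived per sample:

* **Frequencies.** Mononuclear subsets as a percentage of mononuclear
  events; granulocyte subsets as a percentage of all singlet leukocytes
  (their abundance would otherwise swamp the mononuclear simplex). The
  unstimulated aliquot is used: a 15-minute stimulation cannot change
  population abundances, and the basal aliquot is the natural reference.
  Averaging across aliquots would be a defensible alternative; it is not
  taken, to keep each feature attributable to one measurement.
* **Endogenous signaling.** `asinh(median intensity / c)` per
  (population, marker) in the unstimulated aliquot, cofactor `c = 5` (the
  mass-cytometry convention). The median of raw intensities is taken
  *first* and then transformed; transforming per cell and taking the median
  afterward differs numerically and is rejected.
* **Stimulation responses.** The difference of arcsinh-transformed medians
  between a stimulated and the unstimulated aliquot. Because
  `asinh(x/c) ≈ log(2x/c)` for `x ≫ c`, a multiplicative shift `k` of the
  raw signal appears as an additive response `≈ log k`, independent of
  baseline.

A median needs at least `min_cells = 3` events per
(sample, population, condition); rarer combinations are an *error*, not a
blank — downstream models require complete tables and no imputation is
performed. Feature ids are canonical strings `stratum|cell_type|marker`
with a fixed column order (strata in the order freq, Unstim, LPS, IL246,
IL18; then populations in panel order; then markers alphabetically), so a
fitted model's feature list is reproducible byte for byte.

## The penalization matrix

Not every (population, marker, stimulation) combination is biologically
plausible in a 15-minute window: LPS engages TLR4/MyD88, which myeloid
cells express and T cells generally do not; the IL-2/IL-4/IL-6 cocktail
drives JAK/STAT broadly; IL-18 signals through MyD88 mainly in NK, NKT-like
and T subsets. The penalization matrix encodes this as a binary
include/exclude mask; combinations with unclear prior support are retained.

The exact mask used in any given study is curation, so the package ships
two routes: a CSV loader for an externally curated mask, and
`build_penalization_mask()`, which scores each combination by the product
of a receptor-expression weight (per population class) and a
pathway-proximity weight (per marker class) and keeps the top-k per
stimulation stratum. The per-stratum totals are explicit configuration; at
the defaults (248 LPS, 635 IL-2/IL-4/IL-6, 554 IL-18, with frequencies and
the 35 x 20 endogenous grid fully retained) the five strata assemble to
2,172 features per sample. The score table is a coarse rendering of
canonical immunology — it reproduces the *shape* of an expert mask, not any
specific study's curation.

## Classifiers

All models are sparse logistic regressions on standardized features
(training-fold statistics only), fit by `glmnet`:

* **Lasso.** Penalty chosen on a 50-point log-spaced path by 5-fold
  stratified inner cross-validation maximizing pooled out-of-fold AUROC —
  the inner criterion mirrors the outer reporting metric. Ties break
  toward the larger penalty (the sparser model).
* **Adaptive lasso.** Ridge initial coefficients `b0` give per-feature
  weights `w = 1/(|b0|^γ + ε)` (γ = 1, ε = 1e-8); a weighted lasso then
  concentrates the penalty on weakly supported features. `γ = 0` recovers
  the plain lasso.
* **Stability selection.** A Stabl-style decoy-calibrated stability
  selection: 50 half-subsamples
  drawn without replacement, one label-independent permutation decoy
  appended per real feature, per-feature selection frequency taken as the
  maximum per-lambda selection proportion along a shared path, and the
  frequency threshold chosen to minimize the false-discovery-proportion
  proxy `(1 + #decoys ≥ t) / max(1, #real ≥ t)`. When even the minimized
  proxy exceeds `max_fdp = 0.3` the model is declared empty — this is what
  keeps the estimator silent on pure-noise data. Surviving features are
  refit with a ridge-stabilized logistic model (`λ = 0.01`). This
  implementation follows the Stabl idea (decoy-calibrated subsampled
  selection) in spirit, but the permutation-decoy construction and the
  capped threshold rule are this package's own choices, and results may
  diverge from other implementations in detail.
* **Fusion.** Early fusion concatenates the five strata into one design
  matrix. Late fusion fits one model per stratum, collects out-of-fold
  probabilities from an internal stratified 5-fold split (the combiner
  never sees in-fold predictions — the leakage this prevents would
  otherwise inflate the stacker), and trains a logistic combiner on their
  logits. The combiner choice is an assumption; the reference work does
  not specify one.

## Evaluation

Performance is estimated by repeated stratified k-fold cross-validation
(defaults: 5 folds, so 80%/20% splits; the study setting is 200 repeats,
and analyses in this package's test suite use 5–20 repeats to keep runtimes
in seconds — the estimator is identical, only the Monte-Carlo resolution of
the repeat distribution differs). Folds are stratified because the cohorts
are small enough that unstratified splits produce single-class folds with
nontrivial probability. Per repeat, out-of-fold probabilities are pooled
into one AUROC; the summary is the **median across repeats** with a
2.5–97.5% quantile interval. Whether one should pool predictions across all
repeats into a single AUROC instead is ambiguous in the field's reporting;
both are computed (`auroc_per_repeat` retains the distribution) and the
median-of-repeats is the headline. Significance is the two-sided
Mann–Whitney U test comparing cases' and controls' per-sample median
out-of-fold probability — one value per participant, matching how
cross-validated predictions are displayed per arm. The AUROC and the U
statistic are the same quantity (`AUROC = U/n₁n₀`), and the test suite
asserts that duality.

The Mann–Whitney p-value is computed by exact permutation enumeration for
combined n ≤ 20 (enumeration handles ties exactly) and by the normal
approximation with tie and continuity corrections otherwise; the two
branches agree to < 0.03 at the crossover in the test suite.

**Transfer.** A model trained on one cohort is applied unchanged to a
chronologically later cohort; the contract is strict — every training
feature id must be present in the target table (an error names what is
missing), and no refitting occurs.

## Downstream analyses

* **Persistence.** A deliberately less stringent univariate Mann–Whitney
  screen per cohort at unadjusted α = 0.05 (Benjamini–Hochberg q-values are
  reported alongside, clearly labeled, for transparency), then Venn overlap
  of the significant sets across cohorts, with per-cohort directions
  (sign of case-minus-control medians) and a consistency flag for features
  significant everywhere.
* **Confounder adjustment.** "F-statistics on the coefficients" of a
  logistic model is not a standard construct, so two readings are
  reported: the headline is `outcome ~ prediction + confounders` with
  drop-one likelihood-ratio tests per term (the model "remains
  significantly predictive" when the prediction term survives at α =
  0.05); the auxiliary reading is the linear model
  `prediction ~ confounders` with per-term F-tests. Neither is claimed to
  replicate any specific study's numbers. Perfect separation triggers a
  ridge-penalized refit (deviance-difference tests) and a flag.
* **Subtype stratification** among cases (early vs late onset, mild vs
  severe preeclampsia, gestational hypertension vs preeclampsia/HELLP)
  uses the same Mann–Whitney machinery, skipping contrasts with an empty or
  single-member level and flagging groups below `min_n = 5` as
  under-powered.
* **Demographics.** Welch's unequal-variance t-test computable from
  mean/SD/n alone, and the two-sided Fisher exact test (sum of
  hypergeometric point probabilities not exceeding the observed table's).
  Welch is the fixed variant because the published antepartum BMI p-value
  (0.00015) matches Welch (0.000152) and not the pooled-variance test
  (0.00002). One published row (postpartum diastolic blood pressure,
  0.0014) agrees better with the pooled variant (0.00134 vs Welch 0.00118)
  and is therefore excluded from the reproduction checks.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is validated.
Cohort sizes default to the study groups (antepartum 28/38, postpartum
42/37, midlife 70/74). Two routes exist:

* **Event-level** (`generate_events()`): per (sample, condition) aliquot,
  mononuclear counts are Dirichlet-multinomial around sample-specific
  logistic-normal proportions (granulocytes form an extra stratum outside
  the mononuclear simplex, so both frequency denominators are exercised);
  raw intensities are log-normal, so stimulation acts multiplicatively and
  appears approximately additively on the arcsinh scale, matching the
  ratio-of-arcsinh response definition. The canonical response map defaults
  to LPS→pCREB/pNFkB/pERK/pp38/pS6 in monocyte and DC subsets,
  IL-18→pCREB/pNFkB/pp38 in NK/NKT-like cells, and
  IL-2/IL-4/IL-6→STAT phosphorylation in monocytes and T subsets.
* **Sample-level** (`generate_feature_table()`): a direct shortcut drawing
  features from a block-correlated Gaussian on the arcsinh scale
  (block size 10, within-block correlation 0.3) and frequencies from a
  logistic-normal simplex in percent.

Planted case effects are standardized mean shifts on the derived-feature
scale; frequency-stratum effects are applied on the log-weight scale so the
simplex stays valid. No study states cell counts per sample or intensity
distributions, so these are configuration with documented defaults
(1000 mononuclear events per aliquot, log-normal baseline location log 10
and cell-level scale 0.6, between-sample SDs 0.25/0.2/0.3 for baseline,
response and log population weight), chosen as plausible for whole-blood
CyTOF — they are generator settings, not claims about the study. One global
seed streams to per-sample and per-stage child generators, so identical
seed and configuration reproduce tables bitwise while any sample can be
regenerated independently.

Confounders (BMI, age, parity, gestational diabetes, blood pressure, visit
timing) are drawn from arm-specific normal/Bernoulli models whose defaults
reproduce the published per-cohort demographic summaries; they are
correlated with case status only through those arm-specific parameters —
enough structure to exercise the confounder analysis, with no latent
confounder-to-immune pathway.

**What passing tests do and do not show.** The generator produces
uncorrelated-to-weakly-correlated Gaussian features with exchangeable
noise; real CyTOF features have heavier tails, batch structure, long-range
correlation from the gating hierarchy, and biological effect sizes far
below 2 SD. Null calibration, planted-effect recovery, persistence and
transfer results on synthetic data validate the *machinery* (no leakage,
correct statistics, recovery under the stated signal model), not expected
performance on patient data; the published real-data discrimination
estimates are not reproducible from this package and are not claimed by it.

## Numerical choices and degenerate inputs

* Constant feature columns are dropped with a warning before penalized
  fits; an all-constant feature in the univariate screen yields p = 1,
  direction 0.
* Penalty ties in the inner CV break toward the larger lambda; stability
  thresholds tie toward the stricter cut; model-selection ties break
  toward the sparser final model, then candidate order.
* An empty selected set yields an intercept-only model predicting the
  (smoothed) class prevalence.
* Degenerate Welch inputs (both SDs zero) return p = 1 for equal means,
  p = 0 with a degeneracy flag otherwise; zero-margin 2x2 tables return
  p = 1.
* Problem sizes in the test suite: 200-feature spaces (strata
  20/60/40/40/40), cohorts of 30–60 per arm, 5–20 CV repeats, 10–50
  Monte-Carlo seeds per property. These keep the full suite within a few
  minutes while leaving each assertion's Monte-Carlo error well inside its
  tolerance.

## Known limitations

* The stability-selection variant is a documented stand-in for the cited
  method, not a re-implementation of it (see above).
* The knowledge-score mask reproduces per-stratum totals by ranked
  truncation; near the cut the retained set depends on tie-breaking order.
* The confounder analysis offers two defensible readings of an ambiguous
  construct rather than one canonical test.
* Frequencies use the unstimulated aliquot only; real analyses sometimes
  average aliquots.
* No batch effects, acquisition artifacts, debarcoding or gating noise are
  simulated, and FCS ingestion is out of scope — event tables arrive as
  pre-gated CSV exports.
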
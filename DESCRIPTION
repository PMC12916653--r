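Package: persimmune
Title: Immune Feature Derivation and Sparse Case/Control Modeling for
    Mass-Cytometry Immunome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives per-sample immune features from gated single-cell
    mass-cytometry (CyTOF) event data (cell-population frequencies and
    arcsinh-transformed stimulation-response signals under a
    prior-knowledge penalization mask), fits sparse logistic case/control
    classifiers (lasso, adaptive lasso, decoy-calibrated stability
    selection, early and late fusion of stimulation strata) with repeated
    stratified cross-validated AUROC and Mann-Whitney significance, and
    runs downstream analyses: confounder adjustment, cross-cohort model
    transfer, univariate persistence screens with Venn overlap, subtype
    stratification, and demographic comparisons from summary statistics
    (Welch t and Fisher exact tests). Includes a seeded synthetic-data
    generator emulating stimulated whole-blood immune profiling of
    hypertensive-pregnancy case/control cohorts so the full pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
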
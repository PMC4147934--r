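Package: prosig
Title: Signature-Based Molecular Subtyping of Prostate Cancer Expression Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-sample gene-set enrichment (GSEA running-sum) signatures for
    bulk expression cohorts, classification of samples against reference
    molecular subtype profiles using Steiger's test of dependent correlations,
    subtraction of the average normal-tissue signature scaled by histological
    tissue composition, within/between-group signature correlation analysis,
    hierarchical clustering of sample signatures with a same-patient
    cluster-neighbor permutation statistic, and a synthetic cohort generator
    with full ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
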
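Package: kinoviab
Title: Predicting Kinase-Inhibitor-Induced Cell Viability from Kinome
    Inhibition States and Baseline Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end framework linking multi-dose kinome inhibition
    profiles and baseline omics measurements of cancer cell lines to
    drug-induced cell viability. Provides data harmonization of sparse
    kinobead-style inhibition records (default-one densification,
    neighbor-mean gap filling, percentile truncation), imputation of relative
    viability at a shared concentration grid from four-parameter log-logistic
    dose-response parameters, correlation-based feature screening under
    grouped cross-validation, tree-ensemble regression benchmarking and
    ablations, resampling-based protein-interaction enrichment of selected
    genes, prediction for untested cell-line by compound combinations, and
    plate-level validation arithmetic. A synthetic-data module generates all
    pipeline inputs with known ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ranger,
    xgboost,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
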
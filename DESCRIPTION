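Package: metaboscreen
Title: QC-Driven Preprocessing and Biomarker Screening for Untargeted
    LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end statistical workflow for batched untargeted LC-MS
    metabolomic fingerprints with pooled quality-control (QC) injections:
    QC-presence and QC-CV feature filtering, group-presence filtering,
    bracketing-QC within-batch drift correction, log10 transformation,
    PLS-DA and OPLS-DA with 7-fold cross-validation and permutation
    testing, assumption-gated univariate screening (Shapiro-Wilk and
    Levene gates choosing ANOVA or Wilcoxon) with Benjamini-Hochberg FDR
    control, per-feature ROC analysis (Youden threshold, DeLong inference),
    group-median imputation, and SVM leave-one-out classification of
    significant feature panels. Includes a synthetic study generator with
    known ground truth that emulates a multi-batch case-control plasma
    design with scheduled QC injections, signal drift, and below-detection
    missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mixOmics
Config/testthat/edition: 3
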
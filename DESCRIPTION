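Package: secretoscope
Title: Paired Tumor/Juxta-Tumor Secretome Analysis and Tumorness Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplex immunoassay (Luminex/MSD) secretome
    data from paired tumor and adjacent-normal ("juxta-tumor") tissue explants.
    Handles detection-limit censored concentrations (batch-wise LOD imputation),
    low-detection analyte exclusion, paired tumor/juxta ratio analytics and
    univariate tests, a multivariate secretome-based patient distance with
    quantile grouping, PCA with regularized iterative imputation of missing
    cells, hierarchical clustering of log fold-ratios into metamolecules, and a
    stability-aggregated elastic-net classifier of tissue "tumorness" built over
    chained-equations multiple imputation, with ROC-derived cutoff and clinical
    feature association. Includes a synthetic paired-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    caret,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
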
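Package: hiscom
Title: Hierarchical Structural Component Models for Peptide-Level
    Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collapses peptide-level multiple reaction monitoring mass
    spectrometry (MRM-MS) measurements into protein-level latent components
    and fits a doubly ridge-penalized logistic outcome model by alternating
    least squares nested inside iteratively reweighted least squares.
    Includes permutation-based significance testing of protein path
    coefficients, a replicated biomarker-selection screen, ratio-preserving
    train/validation/test splits, AUC-based model comparison against
    unpenalized and ridge logistic baselines, and a simulation framework
    for hierarchically structured peptide data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
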
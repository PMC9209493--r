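Package: apvtools
Title: Multi-Regional 3D Radiomics and the Alzheimer's Predictive Vector
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts multi-regional 3D radiomic features (first-order
    intensity statistics, shape descriptors, grey-level co-occurrence,
    run-length, size-zone, neighbourhood grey-tone difference and
    neighbouring grey-level dependence texture matrices, plus stationary
    wavelet sub-band channels) from labelled T1-weighted-style volumes,
    screens features by Benjamini-Hochberg false discovery rate, and fits
    a two-stage cross-validated LASSO cascade producing Alzheimer's
    Predictive Vector (ApV) scores. Includes the full diagnostic-accuracy
    metric panel (likelihood ratios, diagnostic odds ratio, Youden index),
    one-way intraclass correlation and Bland-Altman repeatability
    statistics, a top-weight feature-subset robustness analysis, and a
    seeded synthetic brain-phantom cohort generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
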
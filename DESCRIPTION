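Package: methyldecon
Title: Robust Reference-Based Deconvolution of Bulk DNA Methylation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates leukocyte subset fractions from bulk DNA methylation
    Beta-value profiles by regressing each mixture against a CpG-by-cell-type
    reference signature matrix. The central solver is a Fast Least Trimmed
    Squares (LTS) regression that discards CpGs carrying signal from unknown
    (for example tumor) content, with linear least squares, non-negative
    quadratic programming, Huber robust regression and nu-support-vector
    regression provided as comparators. Includes goodness-of-fit based
    deconvolution significance calling with ROC calibration on synthetic
    two-component mixtures, random-forest tumor-purity estimation with
    purity-scaled fractions, a signature-matrix builder (bridging batch
    correction, filter cascade, pairwise differential tests,
    condition-number-minimising marker selection), spike-in mixture
    simulators, and a benchmarking harness comparing the five regression
    engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    MASS,
    e1071,
    quadprog,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
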
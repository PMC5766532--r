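Package: metimpute
Title: Missing Value Imputation and Evaluation for Mass Spectrometry
    Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for handling missing values in mass-spectrometry based
    metabolomics abundance tables. Implements eight imputation methods
    (zero, half-minimum, mean, median, sample-wise k-nearest neighbours,
    iterative rank-k SVD, iterative random forest, and QRILC truncated
    normal imputation for left-censored data), simulators for missing
    completely at random and left-censored missing not at random patterns,
    the group-wise modified 80 percent rule filter, and an evaluation
    framework (z-scored NRMSE, NRMSE-based sum of ranks, PCA and PLS-DA
    Procrustes errors, and correlation of log t-test p-values) wired into
    a batch benchmark pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    mixOmics,
    ranger,
    rlang,
    stats,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
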
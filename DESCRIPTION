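Package: sccombo
Title: Single-Cell Pathway Activation Scoring and Combination Therapy
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting intratumoral heterogeneity in drug-target
    pathway activation from single-cell RNA-seq and for turning it into a
    combination-therapy recommendation. Implements cell- and gene-level
    quality filtering for TPM expression matrices, per-sample gene-set
    variation scoring (Gaussian kernel CDF, symmetric rank statistic and a
    weighted Kolmogorov-Smirnov-like random walk), a size-matched random
    gene-set permutation null that binarizes pathway activation calls,
    ridge-regression drug-sensitivity prediction from cell-line training
    panels with batch adjustment and leave-one-out cross-validation,
    four-group classification of cells over a pathway pair, and
    coverage-maximizing selection of a drug pair across tumor
    subpopulations. A synthetic-cohort generator with planted subpopulation
    structure, dropout, batch effects and a linear pathway-activity to
    log-IC50 relationship makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
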
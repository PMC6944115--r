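Package: gliomastrat
Title: Survival-Driven Marker Stratification and Immune Profiling for Glioma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying tumour cohorts by a continuous marker against
    overall survival: digital immunohistochemistry H-score quantification from
    pixel intensity bins, dual expression/survival cutoff search minimising
    Fisher's exact test P-values, constrained log-rank cutoff scans,
    empirical-Bayes moderated differential expression, iterative prognostic
    gene-signature construction, sample-wise rank-based gene-set enrichment
    scoring, and purity-corrected immune cell-type deconvolution by
    non-negative least squares. Includes a synthetic cohort generator with
    known ground truth so every stage is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
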
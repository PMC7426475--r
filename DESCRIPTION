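Package: netsign
Title: Sign-Handling Pipelines for Functional Connectivity Graph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the treatment of anti-correlations in
    resting-state functional connectivity matrices affects graph-theoretic
    classification of clinical groups. Builds binary brain graphs from Pearson
    connectivity matrices under three sign-handling pipelines (positive-only,
    negative-only and absolute value) with proportional thresholding, extracts
    measures of integration, segregation, centrality and resilience, trains a
    regularized multilayer perceptron under leave-one-site-out cross-validation,
    and compares pipelines with Welch and paired t-tests under Holm-Sidak
    correction. Includes a synthetic multi-site cohort generator that emulates
    global-signal-regressed ROI time series with planted group differences in
    modular covariance structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
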
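Package: affectdim
Title: Discrete-Emotion Structure in Facial-Physiology Classifier Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for testing whether five-class emotion
    classifier probability outputs carry discrete-emotion information beyond
    two core-affect dimensions (valence and arousal). Provides stimulus-level
    table input/output and validation, a synthetic-data generator that
    emulates stimulus-level data under competing core-affect and
    discrete-emotion generative regimes, endorsement and accuracy summaries,
    normalized mutual information (NMI) evaluation of complete-linkage
    hierarchical clusterings with permutation tests comparing feature
    representations, PCA reduction with re-clustering, pooled cross-validated
    R-squared comparison of multi-output linear and support vector
    regressions, and split-half reliability of aggregated affect ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
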
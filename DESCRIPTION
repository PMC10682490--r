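Package: suigrad
Title: Resting-State Network Connectivity Along a Suicidality Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing resting-state functional connectomes across
    ordered clinical severity groups (a "suicidality gradient" in major
    depressive disorder). Builds Pearson functional-connectivity matrices
    from ROI time series over a 226-node, 10-network brain partition;
    computes within-network, pairwise between-network and one-versus-others
    connectivity summaries and functional-connectivity-index (FCI) composite
    features; assigns cohesive/incohesive connector/province network roles
    and tracks their trajectory across groups; runs covariate-adjusted group
    tests with Benjamini-Hochberg FDR over the 65 network metrics,
    covariate-controlled behaviour correlations and sex/age heterogeneity
    screens; performs network-based-statistic (NBS) permutation inference on
    edge-wise statistics with conjunction analysis; and evaluates linear
    support-vector-machine classifiers with repeated splits, inner
    cross-validation and label-permutation tests. A synthetic multi-subject
    cohort generator with planted non-monotone gradient effects makes the
    whole pipeline testable end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    e1071,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
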
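Package: co2prof
Title: Staged Expression Profiling and Network Analysis for Ordered-Condition
    Microarray Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for three-condition (ordered-series)
    microarray experiments with few replicates: moderated differential
    expression via the randomized variance model (RVM) F-test with
    Benjamini-Hochberg FDR control; series-test-of-cluster assignment of
    log2-ratio trajectories to integer model profiles with permutation-expected
    counts and exact binomial profile significance; hypergeometric GO/KEGG
    over-representation with an enrichment-ratio filter; a signal-transduction
    network built from significantly correlated gene pairs intersected with a
    directed interaction catalog, ranked by normalized betweenness centrality;
    and 2^-ddCt relative quantification for qPCR validation. A seeded
    synthetic-data generator reproduces the statistical structure every stage
    assumes, so the whole pipeline is testable offline against known truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
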
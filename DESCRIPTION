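Package: poemr
Title: Pairwise Additive eQTL Effects on Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies pairs of expression quantitative trait loci (eQTLs)
    with joint additive effects on groups of expression traits. Implements
    iterative residual-based stepwise eQTL scans, agglomerative construction
    of co-association groups, detection of trait modules governed by a
    specific eQTL pair (poeModules) via hypergeometric overlap tests,
    two-locus interaction tests for epistasis, permutation-based false
    discovery rate estimation, and cis/trans annotation. Ships the single-trait
    stepwise baselines (residual-based and partition-based stepwise
    regression), a synthetic two-locus benchmark generator with known ground
    truth, and ROC-based accuracy scoring for method comparison.
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
    rlang,
    readr,
    jsonlite,
    igraph,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
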
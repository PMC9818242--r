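Package: plbin
Title: Prediction Logic Boolean Implication Networks for Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genome-scale regulatory networks from categorized
    multi-omics data with prediction-logic Boolean implication rules.
    Provides housekeeping-gene calibrated categorization of expression and
    copy-number profiles, binarization of single-cell counts, pairwise
    contingency-table induction of six implication rule types scored by
    scope and precision with one-tailed z-test selection, printed baseline
    methods (correlation relevance networks, entropy and mutual
    information, StepMiner-style Boolean implications, discrete Bayesian
    belief network evaluation), graph-centrality hub-gene prioritization
    with permutation testing, gene-set-based edge validation, and seeded
    synthetic-data generators for all input classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
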
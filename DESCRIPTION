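Package: crohnet
Title: Network Prioritisation and Topological Analysis of Disease
    Susceptibility Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for the network analysis of disease
    susceptibility genes on a protein-protein interaction network:
    random-walk-with-restart prioritisation from a training set, consensus
    selection against an external relatedness ranking, disease sub-network
    extraction, global topological characterisation against an
    Erdos-Renyi ensemble, failure-attack robustness with secondary
    extinctions, 3- and 4-node motif census with a degree-preserving
    switching null, a topological segregation statistic for functional
    classes, and exact enrichment tests (hypergeometric, Fisher,
    binomial with Bonferroni correction). Includes a synthetic-data
    generator producing scale-free interactomes with a planted disease
    module, training and candidate gene sets, noisy relatedness rankings,
    differential-expression tables and topologically cohesive functional
    classes, so that every stage of the analysis can be exercised and
    validated without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
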
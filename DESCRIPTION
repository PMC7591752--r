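Package: cernet
Title: miRNA-Target and miRNA-Sponge (ceRNA) Network Inference from Matched
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stepwise toolkit for uncovering microRNA (miRNA) regulation from
    matched miRNA, lncRNA and mRNA expression profiles of a two-group study.
    Selects differentially expressed genes with an empirical-Bayes moderated t
    statistic, scores candidate miRNA-target pairs with twelve expression-based
    prediction methods (correlation, regression, causal-effect and
    competition-based), benchmarks the methods against experimentally validated
    interactions, mines maximal-biclique miRNA-target regulatory modules,
    infers lncRNA/mRNA miRNA-sponge (ceRNA) networks with the sensitivity
    partial Pearson correlation, selects the sensitivity-correlation cutoff by
    power-law goodness of fit, extracts Markov-cluster sponge modules and hub
    genes, and runs generic hypergeometric over-representation analysis.
    Includes a seeded synthetic-data generator with planted regulation and
    sponge structure so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
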
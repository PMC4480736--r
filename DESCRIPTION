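Package: apoppi
Title: Naive Bayes Evidence Integration for Apoptotic Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interaction networks by integrating
    gene co-expression, domain-domain interaction, cross-species interolog
    and smallest-shared-biological-process evidence with a naive Bayesian
    likelihood-ratio classifier trained on gold-standard positive and
    negative pair sets. Identifies apoptotic hub proteins by four criteria
    (degree, apoptotic connectivity, k-core density and permutation-based
    differential expression) and prioritizes dual kinase targets by
    hub-interactor overlap. Ships a synthetic-data generator with a known
    ground-truth interactome so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
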
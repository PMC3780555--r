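Package: drugCombo
Title: Predicting Effective Drug Combinations from Interaction Networks and Pathway Enrichment
Version: 0.1.0
Authors@R: person("drugCombo", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encodes unordered drug pairs as symmetric feature vectors built
    from chemical-chemical interaction confidence scores, protein-protein
    interaction scores between and within the drugs' target sets, and
    hypergeometric enrichment of network-expanded target sets against pathway
    gene sets. Ranks features by minimum-redundancy maximum-relevance (mRMR),
    selects an optimal subset by incremental feature selection (IFS) with a
    small random-forest classifier under 5-fold cross-validation, and ships a
    synthetic-data generator emulating STITCH/STRING/GMT-shaped inputs with a
    configurable planted signal so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
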
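Package: sparccnet
Title: Sample-Specific SparCC Networks for Compositional Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Correlation inference for compositional taxa-abundance tables
    using the closed-form SparCC estimator, with a per-sample decomposition
    of each correlation into single-sample contributions so that one
    co-occurrence network can be built per individual. Includes bootstrap
    and permutation significance for SparCC correlations, clustering of
    taxa into co-abundance groups (CAGs), co-occurrence network topology
    (hubs, degree distributions, robustness under random node removal),
    and prediction of intervention responders from per-sample network
    features via ROC analysis and penalized regression. A synthetic-data
    generator produces multinomial count tables with known log-normal
    basis correlation structure and cohort phenotypes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    glmnet,
    jsonlite,
    optparse,
    MASS,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
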
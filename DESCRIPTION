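Package: n2vko
Title: Disease-Gene Prioritization from Protein Interaction Networks and
    Biological Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease genes by combining node embeddings
    learned from a protein-protein interaction (PPI) network with binary
    UniProt-style keyword annotations. Embeddings come from second-order
    biased random walks (node2vec) fed to a skip-gram model with negative
    sampling; the concatenated embedding-plus-keyword representation is
    passed through feature selection (minimum-redundancy maximum-relevance,
    t-statistic importance, or backward stepwise AIC), class-imbalance
    correction (SMOTE interpolation or a ROSE-style smoothed bootstrap),
    and a ridge-stabilized logistic classifier evaluated by stratified
    five-fold cross-validated AUC. Includes sub-network sparsity
    diagnostics and synthetic planted-community benchmark generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
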
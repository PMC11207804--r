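Package: bondgat
Title: Bottom-Up Bond-Substructure Graph Attention Networks for Molecular Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ADMET-type molecular properties directly from SMILES with an
    attention-based graph neural network that processes molecules bottom-up: four
    parallel multi-head graph-attention branches, one per bond class (single, double,
    triple, aromatic), are fused by a masked sum, passed through a whole-molecule
    attention layer and a gated global attention pooling, and read out by a small
    multilayer perceptron. Includes the one-hot atom featurization and per-bond-class
    adjacency construction, density-weighted RMSE and log-ratio class-weighted
    binary cross-entropy losses for skewed or imbalanced targets, stratified
    five-fold cross-validation with validation-based epoch selection, an
    AUPRC-first metric suite, a synthetic molecule generator for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
SystemRequirements: Python (>= 3.7) with the rdkit package, available on the
    PATH as 'python' (used for SMILES parsing).
Config/testthat/edition: 3
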
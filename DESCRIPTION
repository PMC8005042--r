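Package: multignn
Title: Multi-GNN Molecular Bioactivity Models and Consensus Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-neural-network regression models for small-molecule
    bioactivity (pIC50) built from composable layer operators: graph
    isomorphism (GIN), graph attention (GAT), ARMA spectral filters and
    simple graph convolution (SGC), combined into the composite GIAN,
    GIAT and SGCA architectures with batch normalization, pooled
    readout and a fixed fully connected regression head. Includes one-hot
    molecular-graph featurization from SMILES (46 atom features with
    coordinate-format edge lists), an early-stopped Adam training loop
    with 10-fold cross-validation, descriptor-based 2D-QSAR baselines
    (variance filtering, standardization, Lasso selection, PCA, random
    forest and support vector regression), a top-50% vote-scoring
    consensus ranker for virtual-screening candidates, and deterministic
    synthetic-molecule generators so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    e1071,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
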
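Package: genoprox
Title: Sparse Proximal-Gradient Deep Residual Networks and Linear Models for
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic adaptive proximal-gradient training of sparse one
    dimensional residual networks and sparse linear models on high-dimensional
    genotype data. Provides closed-form and numerically solved proximal
    operators for twelve convex and non-convex penalties (L0, L1/2, L2/3, L1,
    L4/3, L3/2, L2, L3, L4, max-norm, SCAD, MCP), an Adam-style diagonally
    preconditioned proximal optimizer, 1D residual network architectures for
    marker vectors, a proximal-gradient linear model, evaluation metrics
    (mean squared error, distance correlation, exact Wilcoxon signed-rank,
    weight sparsity), a synthetic genotype/phenotype simulator with tunable
    linkage disequilibrium and heritability, and a cross-validation plus
    hyperparameter-search harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
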
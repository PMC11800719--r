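Package: hierGxE
Title: Hierarchical Selection of Gene-Environment Interactions in
    Penalized Logistic Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint selection of genetic main effects and gene-environment
    interaction (GEI) effects in high-dimensional generalized linear mixed
    models for structured and related samples. Variance components for a
    polygenic and a polygenic-by-environment random effect, with kinship
    and exposure-masked kinship covariance, are estimated once under the
    null by penalized quasi-likelihood (PQL) working-model iterations with
    average-information REML. Fixed effects are then selected along a
    two-dimensional regularization path by a proximal Newton algorithm
    with block coordinate descent under a sparse group lasso penalty that
    enforces strong hierarchy: an interaction can enter the model only
    when its main effect is present. Includes kinship construction from
    standardized genotypes, PLINK 1 binary and GCTA GRM input/output,
    cross-validation over the penalty grid, selection-performance metrics,
    out-of-sample risk prediction with kinship-based random-effect
    transfer, and a synthetic-data generator for structured genotypes and
    binary phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'baseline.R'
    'cli.R'
    'family.R'
    'hierGxE-package.R'
    'io-grm.R'
    'io-plink.R'
    'io-results.R'
    'kinship.R'
    'metrics.R'
    'modelSelection.R'
    'nullModel.R'
    'path.R'
    'prox.R'
    'simulate.R'
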
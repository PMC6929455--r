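Package: rcmf
Title: Robust Collaborative Matrix Factorization for miRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts miRNA-disease associations by robust collaborative
    matrix factorization: a low-rank factorization of the binary
    association matrix with similarity-matching collaborative
    regularizers and an L2,1-norm penalty on the disease factor matrix,
    solved by alternating closed-form least-squares updates with
    iteratively reweighted handling of the L2,1 term and SVD
    initialization. Includes disease semantic similarity from an
    ontology DAG, Gaussian interaction profile kernel similarity,
    weighted K-nearest-known-neighbor preprocessing of missing
    associations, repeated pair-holdout cross-validation with AUC,
    grid search, synthetic fixture generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'semantic.R'
    'factorization.R'
    'similarity.R'
    'synthetic.R'
    'wknkn.R'
    'evaluation.R'
    'io.R'
    'cli.R'
    'rcmf-package.R'
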
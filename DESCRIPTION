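Package: rmrcm
Title: Correlated Mutation Analysis via Regularized Multinomial Regression
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects correlated mutations between columns of a protein
    multiple sequence alignment by regressing each column on the one-hot
    (indicator) expansion of all other columns with an elastic-net penalized
    multinomial model, then projecting the coefficient paths onto a symmetric
    column-column link matrix (BIC-selected, path-sum or model-count scoring).
    Includes a Markov random field Gibbs sampler for generating benchmark
    alignments with known interaction networks, an entropy-corrected mutual
    information baseline, and validation machinery: ROC/AUC against ground
    truth networks, structure-based contact maps with CASP-style accuracy and
    Xd, F-scores, distance enrichment, and log-likelihood scoring of candidate
    molecule pairs for interaction prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
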
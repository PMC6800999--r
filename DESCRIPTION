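Package: ContactFold
Title: Contact-Distance-Driven Protein Folding and Deep-Learning Model Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for residue-residue contact-driven ab initio protein
    structure modelling and for deep-learning-based model quality assessment.
    Predicted contacts are translated into distance restraints under two
    contact energy functions (a bounded quadratic-with-linear-tail potential
    and a square well with exponential decay), folded by metric-matrix
    distance geometry plus simulated annealing in a two-round protocol with
    beta-sheet detection and pruning of unrealized restraints, then clustered
    and selected. A two-level neural-network ensemble (ten cross-validated
    level-1 regressors plus a level-2 combiner) ranks structural models from
    1D secondary-structure/accessibility match features, 2D contact-match
    features and external 3D quality scores, evaluated by GDT-TS selection
    loss. A synthetic-data module generates toy natives, graded decoys and
    precision-controlled contact predictions for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
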
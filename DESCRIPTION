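Package: ppigru
Title: Sequence-Based Protein-Protein Interaction Prediction with
    Bidirectional GRU Feature Reduction and Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions from primary sequence
    alone. Protein pairs are encoded with six complementary descriptors
    (pseudo amino acid composition, autocorrelation descriptors,
    autocovariance, conjoint triads, local composition/transition/
    distribution descriptors, and multivariate mutual information over a
    seven-letter physicochemical alphabet); each descriptor block is reduced
    by a supervised bidirectional GRU sized by an explicit power-of-two rule,
    and the concatenated hidden states are classified by gradient-boosted
    decision trees.  Includes stratified five-fold cross-validation, lag
    optimization, three ensemble strategies, a synthetic pair-set generator
    with tunable compositional signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    rlang,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
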
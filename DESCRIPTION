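Package: echier
Title: Hierarchical Enzyme Commission Number Prediction from Protein
    Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ensemble-based hierarchical prediction of Enzyme Commission
    (EC) numbers from amino-acid sequence alone.  One binary model is
    trained per EC class, combining a subsequence-profile-map SVM, a
    local-alignment k-nearest-neighbour vote, and a physicochemical
    descriptor SVM; the three scores are weighted by cross-validated
    AUROC and the EC hierarchy is traversed top-down with class-specific
    score cutoffs, so a query is labelled with an EC number path,
    "non-enzyme", or "no prediction".  Includes hierarchy-aware negative
    training-set construction, redundancy-reduced train/validation
    splitting, a synthetic motif-family benchmark generator, and
    level-wise evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
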
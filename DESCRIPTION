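Package: rulenet
Title: Interpretation of Tree Ensembles as Regularized Decision Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simplifies fitted tree-ensemble models (random forests, gradient
    boosted trees) into a regularized ensemble of decision rules, quantifies
    the importance and influence of features and of pairwise feature
    interactions, and renders the result as an importance/influence table and
    a decision network. Includes discretization of numeric features into
    levels, rule pruning, bootstrap stability selection of decisions, readers
    for XGBoost JSON dumps and a generic per-node CSV format, converters for
    'ranger' and 'xgboost' model objects, a rule-based simulator of binary
    phenotypes with known ground-truth interaction networks, and evaluation
    utilities (precision/recall against a ground truth, TP/FP curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ranger,
    xgboost,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
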
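Package: sidefx
Title: Similarity-Based Drug Side-Effect Prediction with Multiple-Feature
    Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug side effects (adverse drug reactions) by pairing
    drugs with side effects and classifying each pair from similarity-based
    features. For every pair, a candidate list of association scores between
    the drug and training drugs sharing the side effect is built per
    association type (chemical fingerprint, structure, ATC code, literature
    co-occurrence, protein target), and features are drawn from the sorted
    list under single-, discrete-, or continuous-sampling strategies before
    binary classification. Includes leakage-aware stratified 10-fold
    cross-validation, confusion-matrix metrics (sensitivity, specificity,
    accuracy, MCC, precision, F1), ROC and precision-recall curves with
    AUROC/AUPR, negative-pair sampling for bipartite drug-phenotype data, and
    a synthetic-world generator with planted cluster structure so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
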
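Package: mooncop
Title: Moonlighting Protein Prediction and Misclassification-Based Outlier Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting moonlighting proteins from amino-acid
    sequence. Computes formula-exact sequence descriptors (split amino-acid
    composition, k-spaced pair composition, dipeptide deviation from
    expected mean, composition/transition/distribution, sequence-order
    coupling numbers, quasi-sequence-order, reduced-alphabet k-tuple
    composition and related families), benchmarks classifier families under
    a shared-fold repeated 10-fold cross-validation protocol, and flags
    candidate outlier proteins (possible label errors) by their
    misclassification frequency across repeats, including outlier-set
    statistics, set combination, removal/re-evaluation, and
    repeated-probability scoring of new candidate proteins. Includes a
    synthetic sequence generator with tunable class separation and injected
    label-flipped outliers so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    withr,
    ggplot2,
    generics,
    readr,
    stringr,
    e1071,
    rpart,
    randomForest,
    nnet,
    glmnet,
    class,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
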
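Package: snfimc
Title: miRNA-Disease Association Prediction via Similarity Network Fusion
    and Inductive Matrix Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations by fusing two
    similarity views per entity class (disease semantic similarity and
    Gaussian interaction-profile kernels for diseases; miRNA functional
    similarity and interaction-profile kernels for miRNAs) with similarity
    network fusion, then completing the sparse binary association matrix
    with a nonnegative inductive matrix completion solver driven by
    multiplicative updates. Includes disease semantic similarity over a
    term DAG, leave-one-out and repeated five-fold cross-validation with
    candidate-set ranking, ROC/AUC evaluation, and a synthetic-data
    generator with planted low-rank structure so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
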
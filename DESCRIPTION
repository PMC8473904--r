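Package: clusterpanel
Title: Expression Clustering and Discriminative Gene Panel Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers genomic clusters in high-dimensional gene-expression
    matrices and distills compact discriminative gene panels. Provides
    multi-restart k-means++ clustering with within-cluster sum-of-squares
    elbow analysis, a three-stage feature-selection pipeline (Fisher-score
    filter, linear SVM recursive feature elimination with correlation bias
    reduction, and randomized sequential floating forward search wrapped
    around a k-nearest-neighbour objective with frequency-of-occurrence
    consolidation), classifier-suite cross-validation of the selected panel,
    decision-tree rule extraction, and per-cluster drug-response summaries.
    Includes a synthetic-data generator with planted cluster structure so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    jsonlite,
    mclust,
    nnet,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
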
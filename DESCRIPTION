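Package: degnet
Title: Classification of Differentially Expressed Genes with a Convolutional
    Network and Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Labels genes from two-condition (normal versus tumor) expression
    matrices as up-regulated, down-regulated or neutral using differential
    expression statistics, then trains a convolutional neural network on
    per-gene expression vectors with a two-level scheme: three-class general
    training followed by two-class fine-tuning on a biologically validated
    gene subset after replacing the output head. The trained backbone
    transfers to unseen datasets of any sample count through adaptive
    pooling. Includes a negative-binomial simulator with planted effects,
    a six-metric evaluation suite (accuracy, recall, precision, F-measure,
    Matthews correlation coefficient, ROC-AUC), a Gaussian-noise robustness
    benchmark, and a harness of five classical classifier baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    class,
    randomForest,
    e1071,
    xgboost,
    pROC,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
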
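Package: qdiagnose
Title: Adaptive Diagnostic Classification with Tabular Q-Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reformulates binary diagnostic classification from ordinal
    clinical-instrument items as a Markov decision process. A tabular
    Q-learning policy adaptively selects which item to query next and when
    to commit to a prediction, using a Naive Bayes belief classifier over
    partial observations for intermediate and final rewards. Includes a
    synthetic two-class ordinal data generator with configurable item
    discriminability, combinatorial feature masking and median imputation,
    decision-tree and random-forest baselines (plain and masked-augmented),
    a bootstrapped null F1 threshold, stratified cross-validated robustness
    evaluation under feature omission, and policy interpretation via episode
    traces and empty-state Q-value feature importances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rpart,
    ranger,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
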
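Package: genesim
Title: Ontology-Based Gene Functional Similarity and Stacked Ensemble
    Classification of Disease Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes gene functional similarity from Gene Ontology
    annotations using a hybrid Wang-style semantic similarity whose edge
    weights derive from term children counts, and classifies disease genes
    from the resulting similarity matrix. Includes from-scratch resamplers
    for imbalanced data (SMOTE, random undersampling and their hybrid), a
    gradient-boosting classifier with small random forests as weak
    learners, two-level stacked generalization over standard base
    learners, stratified cross-validation with the usual binary metrics,
    and synthetic generators (random rooted DAGs, class-structured
    annotation cohorts, Gaussian blobs) for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    e1071,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
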
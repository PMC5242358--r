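Package: rxclassify
Title: Disease Classification from Outpatient Prescriptions via Drug-Group Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies outpatient prescriptions into disease classes from
    drug-group count vectors. Provides a synthetic prescription-data
    generator with controllable class signatures, overlap and noise; the
    normalized shared-drug-group ("naive") baseline classifier; a bank of
    six configured base learners (decision tree, polynomial-kernel support
    vector machine, single-hidden-layer neural network, naive Bayes,
    ridge-penalized multinomial logistic regression, Manhattan-distance
    nearest neighbour); hard-label combining by majority voting, weighted
    voting with a multiplicative update rate, and stacked generalization
    with a cross-validation-built meta-dataset; and stratified k-fold
    cross-validated evaluation reporting per-class sensitivity, specificity
    and precision with pooled confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
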
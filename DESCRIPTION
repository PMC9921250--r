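Package: clinstack
Title: Hybrid Feature Selection and Probability-Augmented Stacking for
    Clinical Tabular Classification
Version: 0.1.0
Authors@R:
    person("clinstack", "developers", email = "clinstack@example.org",
           role = c("aut", "cre"))
Description: A schema-agnostic toolkit for binary classification of clinical
    tabular data. Provides declarative dataset schemas with range-aware CSV
    ingestion, a seeded synthetic data generator with planted informative
    features, an automated preprocessing pipeline (duplicate removal, KNN and
    label-distribution imputation, isolation-forest outlier removal, class
    rebalancing and distribution-aware scaling), a hybrid voting feature
    selection framework aggregating six rankers, six heterogeneous base
    classifiers (regularised logistic regression, RBF support vector machine,
    gradient-boosted trees, random forest, multilayer perceptron and a 1-D
    convolutional network), and a two-layer stacking classifier whose
    meta-layer consumes both the class decisions and the decision
    probabilities of the base models. Includes stratified k-fold evaluation
    with sensitivity/specificity reporting and a configuration-driven
    command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet,
    quadprog,
    truncnorm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
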
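Package: phenobench
Title: Benchmarking Machine Learning and Statistical Genetics Methods for
    Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for benchmarking genomic phenotype prediction.
    Implements genomic BLUP with REML variance components, a sequential
    QTL forward-selection predictor with permutation-based false discovery
    rate thresholds, uniform wrappers around penalised regression, random
    forest, gradient boosting and support vector regression with
    nested-tuning cross-validation, rank-based method comparison
    (tie-corrected Friedman test and Nemenyi post-hoc), phenotype and
    genotype degradation experiments, gene-level marker fusion, multi-task
    trait stacking, and a meiosis simulator for biparental crosses and
    structured breeding populations so the full protocol can be exercised
    end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    ranger,
    xgboost,
    kernlab,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
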
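Package: littriage
Title: Hierarchical Triage of Biomedical Literature with Ensemble Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for (semi-)automatic triage of biomedical publications into a
    nested study-design taxonomy (classes, subclasses, sub-subclasses), as used
    by living systematic reviews. Provides probability roll-ups between taxonomy
    levels, probability-sum and thresholded-voting ensembles with abstention and
    dynamic thresholds, a complete evaluation battery (per-label and aggregate
    classification metrics, one-vs-rest AUC-ROC, bootstrap confidence intervals,
    McNemar paired comparison, precision/recall/MAP at k, coverage-performance
    grids), integrated-gradient word-impact aggregation, a reference multinomial
    text classifier, and synthetic corpus and prediction simulators so every
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
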
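Package: mepbench
Title: Benchmarking and Ensemble Voting of Missense Mutation Effect Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking missense variant effect prediction
    algorithms against a functionally validated truth set of neutral and
    non-neutral single nucleotide variants. Harmonizes heterogeneous
    predictor output (raw categories and numeric scores, with optional
    low-confidence bands) into common call categories, quantifies
    inter-predictor agreement with unweighted Cohen's kappa and
    complete-linkage hierarchical clustering on Hamming distances,
    computes accuracy, sensitivity, specificity, predictive values and a
    composite score with bootstrap confidence intervals, and exhaustively
    enumerates and evaluates n-of-p majority-vote ensembles of single
    predictors with split-sample resampling and rule ranking. Includes a
    synthetic-data generator for correlated rater panels so that every
    stage of the analysis can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
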
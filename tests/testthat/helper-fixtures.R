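# Shared fixtures, all built in code.

# A tiny raw call table with two score-free synthetic predictors.
make_toy_table <- function() {
  variants <- data.frame(
    variant_id = c("TP53:p.R175H", "BRAF:p.V600E", "BRCA1:p.M1V"),
    gene = c("TP53", "BRAF", "BRCA1"),
    gene_class = c("tsg", "oncogene", "tsg"),
    truth_label = c("non_neutral", "non_neutral", "neutral"),
    in_cosmic = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  raw <- matrix(c("non_neutral", "non_neutral", "neutral",
                  "non_neutral", "equivocal", "neutral"),
                ncol = 2, dimnames = list(NULL, c("raterA", "raterB")))
  raw_call_table(variants, raw)
}

toy_specs <- function(names = c("raterA", "raterB")) {
  synthetic_rater_specs(names)
}

# Write a small TSV that read_variant_call_table() can parse.
write_toy_tsv <- function(path, truth = c("non_neutral", "neutral", "uncertain"),
                          ids = c("TP53:p.R175H", "BRAF:p.V600E", "KRAS:p.G12D")) {
  df <- data.frame(
    variant_id = ids,
    gene = sub(":.*", "", ids),
    gene_class = c("tsg", "oncogene", "oncogene"),
    truth_label = truth,
    in_cosmic = c(TRUE, FALSE, TRUE),
    raterA_call = c("non_neutral", "neutral", "neutral"),
    raterA_score = c(NA, NA, NA),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# Per-predictor performance expectations derived from the shipped
# cross-tabulations (percentages to 2 dp, composite to 4 dp).
expected_panel_stats <- function() {
  read.table(header = TRUE, sep = ",", strip.white = TRUE,
             stringsAsFactors = FALSE, text = '
predictor, accuracy, sensitivity, specificity, ppv, npv, composite
CHASM (breast), 88.68, 89.99, 80.71, 96.59, 57.07, 3.2436
CHASM (lung), 90.09, 92.23, 77.14, 96.07, 62.07, 3.2751
CHASM (melanoma), 89.69, 93.64, 65.71, 94.31, 63.01, 3.1667
FATHMM (cancer), 91.00, 97.88, 49.29, 92.13, 79.31, 3.1860
FATHMM (missense), 82.51, 87.75, 50.71, 91.52, 40.57, 2.7056
Mutation Assessor, 74.70, 76.65, 62.86, 92.59, 30.77, 2.6287
MutationTaster, 88.57, 90.81, 75.00, 95.66, 57.38, 3.1885
PolyPhen-2, 79.78, 84.22, 52.86, 91.55, 35.58, 2.6420
PROVEAN, 73.71, 74.44, 69.29, 93.63, 30.89, 2.6825
SIFT, 80.99, 86.10, 50.00, 91.26, 37.23, 2.6460
VEST, 75.03, 82.69, 28.57, 87.53, 21.39, 2.2018
CanDrA (breast), 81.81, 95.38, 0.00, 85.19, 0.00, 1.8056
CanDrA (lung), 91.28, 92.86, 80.95, 96.97, 63.35, 3.3413
CanDrA (melanoma), 88.97, 90.73, 77.60, 96.33, 56.40, 3.2105
Condel, 85.84, 92.58, 45.00, 91.08, 50.00, 2.7866
')
}

# Performance stats for every fixture predictor, via the cross-tab
# expansion path (shared by several test files).
fixture_panel_stats <- function(seed = 1L) {
  cts <- load_benchmark_crosstabs()
  lapply(cts, function(ct) {
    d <- calls_from_crosstab(ct, seed = seed)
    performance_stats(confusion_counts(d$call, d$truth_label))
  })
}
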
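# mepbench

Benchmarking missense mutation effect predictors against a functionally
validated truth set, and searching n-of-p voting ensembles that improve
on any single predictor.

## What it is for

Cancer sequencing studies produce long lists of missense single
nucleotide variants (SNVs), and computational effect predictors (SIFT,
PolyPhen-2, CHASM, FATHMM, PROVEAN, VEST, MutationTaster, Mutation
Assessor, Condel, CanDrA, ...) are the standard triage tools — but they
disagree, sometimes wildly. `mepbench` is for anyone who has a table of
per-variant predictor calls plus a set of variants with experimentally
established effect (non-neutral / neutral), and wants to know:

* how well does each predictor classify the validated variants
  (accuracy, sensitivity, specificity, PPV, NPV, and a composite score
  = sensitivity + specificity + PPV + NPV, with bootstrap CIs);
* how much do the predictors agree with each other (pairwise
  unweighted Cohen's κ, complete-linkage clustering on Hamming
  distances, Newick export);
* can a voting combination do better — every rule "call the variant
  non-neutral if ≥ p of these n single predictors do" is enumerated
  (11 predictors → 11,253 rules), evaluated over repeated 2/3 : 1/3
  split samples, ranked, and tested against the best single and meta
  predictors by the CI-overlap significance rule.

A synthetic-data module generates correlated rater panels with known
sensitivity/specificity/equivocal rates and a planted cluster
structure, so the whole pipeline is testable without any external data.
The package also ships, as a plain-text fixture, the published
cross-tabulations of 3,591 annotated SNVs (849 non-neutral, 140
neutral, 2,602 uncertain) by 15 predictors, from which all headline
performance statistics are recomputable.

## The statistics at the core

With non-neutral as the positive class and equivocal calls and
truth-uncertain variants excluded from the confusion table:

    sensitivity = TP / (TP + FN)        PPV = TP / (TP + FP)
    specificity = TN / (TN + FP)        NPV = TN / (TN + FN)
    accuracy    = (TP + TN) / (TP + TN + FP + FN)
    composite   = sensitivity + specificity + PPV + NPV   (0 .. 4)

Agreement: κ = (p_o − p_e) / (1 − p_e) over pairwise-definite calls.
CIs: percentile bootstrap over variants (1,000 iterations). Two
estimates differ significantly when their 95% CIs touch or do not
overlap; in standard-error form z = 2(se₁+se₂) / √(se₁²+se₂²).
Ensembles: a rule (members, p) votes non-neutral when ≥ p members do;
equivocal members abstain without shrinking the threshold.

## Worked example

Recompute every predictor's performance from the shipped
cross-tabulations:

```r
library(mepbench)

stats <- lapply(load_benchmark_crosstabs(), function(ct) {
  d <- calls_from_crosstab(ct, seed = 1)           # exact expansion
  performance_stats(confusion_counts(d$call, d$truth_label))
})
stats[["FATHMM (cancer)"]]
#> accuracy      91.00%
#> sensitivity   97.88%
#> specificity   49.29%
#> ppv           92.13%
#> npv           79.31%
#> composite    3.1860
cohort_summary(stats)
#>        metric median    min    max
#> 1    accuracy 85.844 73.711 91.282
#> 2 sensitivity 90.729 74.441 97.880
#> 3 specificity 62.857  0.000 80.952
#> 4         ppv 92.593 85.185 96.966
#> 5         npv 50.000  0.000 79.310
#> 6   composite  2.787  1.806  3.341
```

FATHMM (cancer) calls nearly every validated non-neutral variant
correctly (sensitivity 97.88%) but only half the neutral ones
(specificity 49.29%); across the panel, PPV is uniformly high while NPV
ranges from 0% to 79% — the spread that motivates ensemble voting.

An end-to-end ensemble search on a synthetic benchmark-like panel:

```r
raters <- benchmark_raters()                 # 15 raters, 2 clusters + outlier
cfg    <- simulation_config(raters, seed = 2024)
m      <- build_call_matrix(
            simulate_call_matrix(simulate_truth_labels(cfg), cfg),
            synthetic_rater_specs(raters))

singles <- raters$name[raters$kind == "single"]
rules   <- enumerate_rules(singles)          # 11,253 rules
ev      <- evaluate_over_splits(rules, m,
             config = split_config(repetitions = 100, seed = 91))
ranked  <- rank_rules(ev, by = "accuracy")
head(np_grid_summary(ev))
```

A thin command-line wrapper with `simulate`, `performance` and
`ensembles` subcommands is provided in `inst/scripts/mepbench.R`.

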
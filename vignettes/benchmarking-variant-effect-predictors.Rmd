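---
title: "Benchmarking mutation effect predictors and n-of-p voting ensembles"
author: "mepbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking mutation effect predictors and n-of-p voting ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepbench)
```

## The problem

Massively parallel sequencing of tumors yields long lists of missense
single nucleotide variants (SNVs), most of which occur in only a small
fraction of cancers of a given site. Computational mutation effect
predictors (SIFT, PolyPhen-2, CHASM, FATHMM, PROVEAN, VEST,
MutationTaster, Mutation Assessor, and the consensus tools Condel and
CanDrA, among others) are the standard triage instruments, but they are
trained on different data, built on different features, and frequently
contradict one another. `mepbench` implements the complete analysis
needed to benchmark such a panel against a functionally validated truth
set:

1. **Harmonization** of heterogeneous raw output (categories and/or
   scores, with optional low-confidence bands) into a common vocabulary:
   `non_neutral`, `neutral`, `equivocal`, and optionally
   `low_confidence`.
2. **Agreement**: pairwise unweighted Cohen's kappa and complete-linkage
   hierarchical clustering on Hamming distances between call vectors.
3. **Performance**: accuracy, sensitivity, specificity, PPV, NPV and a
   composite score against truth labels, with percentile bootstrap
   confidence intervals and a CI-overlap significance rule.
4. **Ensembles**: exhaustive enumeration of n-of-p majority-vote rules
   over the single predictors, evaluated by repeated split-sample
   resampling, ranked, and compared against the best single and meta
   predictors.
5. **Synthetic data**: a correlated-rater generator so that every stage
   is testable end to end without any external download.

The truth set the package's regression fixtures describe contains 3,591
SNVs in 15 cancer genes: 849 validated non-neutral, 140 validated
neutral and 2,602 of uncertain significance. Performance is always
assessed on the 989 labelled variants; uncertain variants participate
only in the agreement analyses.

## Harmonization model and parameters

Each predictor is described by a `predictor_spec()`:

* a **category map** (matched case-insensitively) merging the tool's
  native classes into the common vocabulary. Damaging / functional /
  driver / deleterious-style classes map to `non_neutral`; tolerated /
  neutral / passenger / benign-style classes to `neutral`. Three native
  classes denote an absent verdict and map to `equivocal`: CanDrA
  "no-call", Mutation Assessor "N/A" and FATHMM (missense) "No
  weights". The equivocal convention is not cosmetic: the Mutation
  Assessor sensitivity denominator (848 rather than 849) only
  reproduces when its single N/A-labelled non-neutral variant is
  excluded from the confusion table.
* an optional **score rule** `(direction, cutoff)` for tools defined by
  a threshold: CHASM calls drivers at score ≤ 0.3 (scores are
  passenger-probability-like, unitless in [0, 1]), VEST calls
  functional at ≥ 0.5, PROVEAN deleterious at ≤ −2.5 (an alignment
  delta score), SIFT damaging at ≤ 0.05 (a tolerance probability), and
  FATHMM (cancer) at ≤ −0.75 (a log-odds-style weight). All cutoffs are
  *inclusive on the calling side*, a literal reading of the tools'
  documented defaults. A mapped raw category takes precedence over the
  score; the score rule is consulted when the category is missing or
  unmapped.
* optional **low-confidence rules** for three-category mode: either a
  closed score band (CHASM 0.25–0.35, FATHMM (cancer) −1.65–0.1,
  FATHMM (missense) −2.5–0, PROVEAN −4.1 to −1.3, SIFT 0.04–0.1, VEST
  0.45–0.55, Condel 0.489–0.547, MutationTaster probability ≤ 0.95) or
  a category set (PolyPhen-2 "possibly damaging", Mutation Assessor
  "low", CanDrA "no-call"). Band boundaries are inclusive. A
  pre-specified low-confidence *category* wins outright — including
  CanDrA's "no-call", which is equivocal in binary mode but is that
  tool's own limited-confidence class — whereas score *bands* only
  reclassify definite calls.

Two deliberate conventions cover gaps that any such harmonization must
decide:

* **Missing cells.** A cell with neither category nor score becomes
  `equivocal` and is counted in a message. Whether the original
  analysis excluded or imputed such predictions is unknowable from the
  published tables; exclusion via the equivocal route is the
  conservative choice and is what the confusion-table conventions
  already do.
* **MutationTaster low confidence** is defined on its reported
  probability, so its score column must carry that probability; a
  table without it simply yields no low-confidence calls for that
  predictor.

The SIFT 0.04–0.1 band is shipped as a constant; the package does not
re-derive it from a score-density heuristic.

## Agreement

`cohen_kappa()` computes unweighted kappa over the variants where
*both* raters made a definite call; equivocal pairs are dropped and the
number of variants actually compared is reported. This matches the
convention of converting calls to a two-category vocabulary before
computing agreement. `interpret_kappa()` applies the conventional
qualitative bands (< 0 none, ≤ 0.20 slight, ≤ 0.40 fair, ≤ 0.60
moderate, ≤ 0.80 substantial, ≤ 1 almost perfect).

The clustering distance deliberately uses a different convention: the
Hamming distance treats every call category (including `equivocal` and
`low_confidence`) as its own symbol, so no variants are dropped and an
abstaining predictor is far from a committal one. Both conventions are
visible in the output (`n_used` in kappa results; the distance matrix
itself). Trees are built with complete linkage via `stats::hclust`,
which guarantees monotone merge heights; ties between equal merge
distances are resolved deterministically by column order, so a fixed
input order yields a fixed tree. Trees export to Newick via `ape`, with
merge heights as branch lengths.

Kappa confidence intervals, when requested, come from the same
percentile bootstrap over variants used everywhere else in the package
(default 1,000 iterations) rather than an asymptotic variance formula —
one uncertainty machinery throughout.

## Performance statistics

With `non_neutral` as the positive class,

* sensitivity = TP / (TP + FN) over validated non-neutral variants,
* specificity = TN / (TN + FP) over validated neutral variants,
* PPV = TP / (TP + FP), NPV = TN / (TN + FN),
* accuracy = (TP + TN) / (TP + TN + FP + FN),
* composite = sensitivity + specificity + PPV + NPV (unrounded, range
  0–4).

Uncertain variants and equivocal calls are excluded from all cells and
tallied separately. Metrics with zero denominators are defined as 0,
not `NA` — a predictor that never emits a neutral call genuinely has 0%
specificity and 0% NPV, and this is how such degenerate classifiers are
conventionally reported.

Confidence intervals are percentile bootstrap over variants (default
1,000 iterations, seed-deterministic), resampling the labelled set
without stratification by truth label; a stratified variant of the
analysis can be had by resampling within `stratified_performance()`
subsets. `ci_significance()` implements the standard-error form of the
rule that two bootstrap estimates differ significantly when their 95%
CIs touch or do not overlap: for standard errors $se_1, se_2$ the
just-touching mean difference is $2(se_1+se_2)$, the SE of the
difference is $\sqrt{se_1^2+se_2^2}$, and
$z = 2(se_1+se_2)/\sqrt{se_1^2+se_2^2} \in [2, 2\sqrt2]$, whose normal
tail is always below 0.05 — the formula *encodes* the CI-touch rule
rather than testing an observed difference. Operationally, therefore,
the ranking machinery flags a significant improvement by the direct
test: a higher mean whose percentile CI is separated from (or exactly
touches) the baseline's CI.

```{r fixture-example}
stats <- lapply(load_benchmark_crosstabs(), function(ct) {
  d <- calls_from_crosstab(ct, seed = 1)
  performance_stats(confusion_counts(d$call, d$truth_label))
})
stats[["FATHMM (cancer)"]]
cohort_summary(stats)
```

## Voting ensembles

`enumerate_rules()` generates every subset of $n$ single predictors
($2 \le n \le N$) paired with every vote threshold $p \le n$; a variant
is called non-neutral when at least $p$ members vote non-neutral. An
equivocal member abstains: it contributes no vote and the threshold
stays at $p$, so the ensemble itself never outputs `equivocal`. For the
11 single predictors this yields $11 \cdot 2^{10} - 11 = 11{,}253$
rules. $p = 1$ is the OR rule (sensitivity can only rise above every
member's), $p = n$ the AND rule (specificity can only rise); these
dominance relations and the monotone sensitivity/specificity trade-off
in $p$ are property-tested.

Rules are evaluated by split-sample resampling: the labelled variants
are divided into subset 1 (two-thirds, size by round-half-up: 989 →
659/330) and subset 2, the split repeated (default 1,000 times; the
test suite and examples use 100, which leaves across-split CI estimates
stable at a fraction of the cost), and each rule's metrics summarised
per subset by mean, percentile 95% CI and SD across repetitions.
Splitting is unstratified by default — with only 140 neutral variants a
one-third subset carries ~46 of them, so a `stratified = TRUE` option
exists for balance-sensitive uses. Everything is deterministic given
the configuration seed: each repetition derives its own RNG stream, so
any slice of the rule space reproduces its rows exactly.

`rank_rules()` ranks per subset by mean accuracy and by mean composite
(ties broken by the other criterion, then lexicographically) and flags
each rule against the supplied baselines (typically the best single and
best meta predictor, evaluated as singleton rules under the *same*
splits): numerically higher in both subsets, and CI-separated per
subset. In synthetic panels mirroring the benchmark's operating points,
OR-pairs reliably separate from the best single rater's NPV in the
two-thirds subset; the one-third subset's across-split CIs are usually
too wide for separation there, which is why the flags are reported per
subset rather than only jointly. `recurrence_in_top()` and
`np_grid_summary()` summarise which predictors recur among the top-k
rules and where in the $(n, p)$ grid accuracy peaks; the grid is
reported empirically, with nothing hard-coded about the optimal shape.

## The synthetic-data generator

`simulate_truth_labels()` + `simulate_call_matrix()` emulate the
features of the benchmark that the analysis machinery actually depends
on:

* the truth composition (defaults 849 / 140 / 2,602) and marginal
  gene-class (14.7% oncogene, 79.4% TSG, 5.9% new cancer gene) and
  COSMIC-membership (52.7%) proportions of the cohort;
* per-rater sensitivity, specificity and equivocal rate
  (`benchmark_raters()` carries the 15 benchmark predictors' observed
  operating points, e.g. FATHMM (cancer) 0.9788/0.4929, VEST
  0.8269/0.2857, and no-call rates such as CanDrA (lung) 207/3,591);
* block-correlated errors: a Gaussian one-factor copula per cluster.
  Each variant draws one latent $Z_c \sim N(0,1)$ per cluster; rater
  $j$ in cluster $c$ thresholds
  $\sqrt{\rho}\,Z_c + \sqrt{1-\rho}\,\varepsilon_{ij}$ so its marginal
  correctness equals its configured sensitivity or specificity. This is
  the minimal generative structure that reproduces a two-cluster-plus-
  outlier agreement pattern; the published analysis implies the
  pattern, not a mechanism, so the copula is this package's own
  modelling choice. The default within-cluster correlation is 0.6,
  which puts within-cluster kappas in the moderate-to-substantial range
  and between-cluster kappas near the truth-induced floor — the regime
  the observed panel occupies. Calls on truth-uncertain variants use a
  configurable positive rate (default: the panel's mean positive rate
  on labelled variants) through the same latent factor.

`simulate_scores()` then draws numeric scores consistent with each call
(correct side of the cutoff) that land inside the low-confidence band
at a configured rate, and `calls_from_crosstab()` exactly inverts a
printed cross-tabulation into per-variant calls — the bridge that makes
every published point estimate recomputable from shipped counts.

What the generator does **not** emulate: gene- and tissue-specific
behaviour (the real CanDrA flips wholesale between genes), realistic
score distributions (uniform within intervals, not density-shaped),
training-set leakage between raters and truth labels, and per-variant
difficulty. Tests passing on synthetic panels therefore validate the
*machinery* — calibration, exclusion rules, determinism, dominance
properties, cluster recovery — not any claim about how real predictors
will rank on new data.

## Numerical choices and degenerate inputs

* Score cutoffs inclusive on the calling side; low-confidence bands
  closed intervals.
* 0/0 metrics are 0; an all-equivocal predictor is an error (empty
  confusion table), not a silent zero.
* Kappa of two identical constant raters is 1; one constant rater
  against a varying one gives 0 (observed = chance agreement).
* Subset sizes round half-up; a split that would empty a subset is an
  error.
* All RNG consumers (`simulate_*`, `bootstrap_cis`, `split_dataset`,
  `calls_from_crosstab`, kappa bootstrap) derive child seeds from a
  single base seed and restore the caller's RNG state, so results are
  reproducible and composable.
* Problem sizes in the shipped tests: calibration checks use 3,000–
  8,000 variants (3 binomial SEs is then a tight bound), cluster
  recovery 3,000 variants × 6 raters at ρ = 0.8, and the end-to-end
  ensemble run the full 11,253-rule space at 100 repetitions — sizes
  chosen to make the checks sharp while keeping the suite quick on a
  laptop.

## Known limitations

* The package evaluates predictions; it does not run any of the 15
  external prediction tools or parse their native output formats.
* The CI-overlap significance rule is conservative relative to a
  proper difference test on paired resamples; it is implemented because
  it is the analysis's published decision rule.
* Bootstrap CI *bounds* are seed-dependent by nature; only point
  estimates are exact regression targets.
* With 140 neutral variants, specificity and NPV estimates are noisy,
  and largely driven by TSG variants — a property of the truth set, not
  of the software, but one that any interpretation should carry.
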
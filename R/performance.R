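#' Confusion counts of harmonized calls against truth labels
#'
#' Tallies true/false positives and negatives treating `non_neutral` as
#' the positive class. Variants whose truth label is `uncertain` and
#' variants without a definite call (equivocal or low-confidence) are
#' excluded from all confusion cells and reported in the exclusion
#' counters, matching the convention that performance is assessed only on
#' functionally validated variants that the predictor actually called.
#'
#' @param calls Character call vector.
#' @param truth Character truth-label vector of the same length.
#' @return An object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `n_excluded_equivocal` (labelled variants without a definite call)
#'   and `n_excluded_uncertain`.
#' @export
confusion_counts <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("calls and truth differ in length")
  }
  labelled <- truth %in% TRUTH_LEVELS[1:2]
  definite <- calls %in% CALL_LEVELS[1:2]
  use <- labelled & definite
  structure(
    list(
      tp = sum(use & calls == "non_neutral" & truth == "non_neutral"),
      fp = sum(use & calls == "non_neutral" & truth == "neutral"),
      tn = sum(use & calls == "neutral" & truth == "neutral"),
      fn = sum(use & calls == "neutral" & truth == "non_neutral"),
      n_excluded_equivocal = sum(labelled & !definite),
      n_excluded_uncertain = sum(!labelled)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d (excluded: %d equivocal, %d uncertain)\n",
              x$tp, x$fp, x$tn, x$fn,
              x$n_excluded_equivocal, x$n_excluded_uncertain))
  invisible(x)
}

# Metric vector from count scalars/vectors; the 0/0 -> 0 convention keeps
# degenerate classifiers (e.g. one that never predicts neutral) at 0
# rather than NA, matching how such predictors are reported.
metrics_from_counts <- function(tp, fp, tn, fn) {
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  ppv <- safe_ratio(tp, tp + fp)
  npv <- safe_ratio(tn, tn + fn)
  list(
    accuracy = safe_ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    composite = sens + spec + ppv + npv
  )
}

METRIC_NAMES <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                  "composite")

#' Performance statistics from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value (as proportions) and the composite score, defined as
#' the unrounded sum of sensitivity, specificity, PPV and NPV (range
#' 0-4). Metrics with a zero denominator are reported as 0.
#'
#' Bootstrap confidence intervals require the per-variant calls, so they
#' are attached via the `bootstrap` argument: a list with elements
#' `calls`, `truth` and optionally `iterations` and `seed`, forwarded to
#' [bootstrap_cis()].
#'
#' @param counts A [confusion_counts()] object.
#' @param bootstrap Optional bootstrap configuration (see above).
#' @return An object of class `performance_stats`: the six metrics, the
#'   counts, and (when bootstrapped) per-metric percentile CIs (`ci`) and
#'   bootstrap standard errors (`se`).
#' @export
performance_stats <- function(counts, bootstrap = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn < 1 && counts$tn + counts$fp < 1) {
    stop("empty confusion table: no labelled variant received a definite call")
  }
  m <- metrics_from_counts(counts$tp, counts$fp, counts$tn, counts$fn)
  out <- c(m, list(counts = counts, ci = NULL, se = NULL))
  if (!is.null(bootstrap)) {
    bs <- bootstrap_cis(bootstrap$calls, bootstrap$truth,
                        iterations = bootstrap$iterations %||% 1000L,
                        seed = bootstrap$seed %||% 1L)
    out$ci <- bs$ci
    out$se <- bs$se
  }
  structure(out, class = "performance_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.performance_stats <- function(x, ...) {
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("%-12s %6.2f%%", nm, 100 * x[[nm]]))
    if (!is.null(x$ci)) {
      cat(sprintf("  (%.2f-%.2f%%)", 100 * x$ci[[nm]][1], 100 * x$ci[[nm]][2]))
    }
    cat("\n")
  }
  cat(sprintf("%-12s %6.4f", "composite", x$composite))
  if (!is.null(x$ci)) {
    cat(sprintf("  (%.4f-%.4f)", x$ci$composite[1], x$ci$composite[2]))
  }
  cat("\n")
  invisible(x)
}

#' Bootstrap confidence intervals for the performance metrics
#'
#' Resamples variants with replacement and recomputes the six metrics in
#' each iteration; returns percentile confidence intervals and the
#' bootstrap standard error (the standard deviation of the resampled
#' metric) for each. Deterministic for a fixed seed.
#'
#' @param calls Character call vector.
#' @param truth Matching truth-label vector; at least one labelled
#'   variant is required.
#' @param iterations Number of bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `ci` (named list of `c(low, high)` per metric),
#'   `se` (named numeric vector) and `iterations`.
#' @export
bootstrap_cis <- function(calls, truth, iterations = 1000L, seed = 1L,
                          conf_level = 0.95) {
  if (length(calls) != length(truth)) {
    stop("calls and truth differ in length")
  }
  stopifnot(iterations >= 1L)
  if (!any(truth %in% TRUTH_LEVELS[1:2])) {
    stop("no labelled variants to resample")
  }
  n <- length(calls)
  pos <- calls == "non_neutral"
  neg <- calls == "neutral"
  is_nn <- truth == "non_neutral"
  is_ne <- truth == "neutral"
  draws <- with_seed(seed, {
    out <- base::matrix(NA_real_, iterations, length(METRIC_NAMES),
                        dimnames = list(NULL, METRIC_NAMES))
    for (i in seq_len(iterations)) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- metrics_from_counts(
        tp = sum(pos[idx] & is_nn[idx]),
        fp = sum(pos[idx] & is_ne[idx]),
        tn = sum(neg[idx] & is_ne[idx]),
        fn = sum(neg[idx] & is_nn[idx])
      )
      out[i, ] <- unlist(m)[METRIC_NAMES]
    }
    out
  })
  alpha <- (1 - conf_level) / 2
  ci <- lapply(METRIC_NAMES, function(nm) {
    stats::quantile(draws[, nm], c(alpha, 1 - alpha), names = FALSE)
  })
  names(ci) <- METRIC_NAMES
  se <- apply(draws, 2, stats::sd)
  list(ci = ci, se = se, iterations = iterations)
}

#' Significance of a difference by the CI-overlap rule
#'
#' Implements the standard-error form of the rule that a difference
#' between two bootstrap estimates is statistically significant when
#' their 95% confidence intervals touch or do not overlap. Writing the
#' two standard errors \eqn{se_1} and \eqn{se_2}, the just-touching
#' difference between the means is \eqn{2(se_1 + se_2)} while the
#' standard error of the difference is \eqn{\sqrt{se_1^2 + se_2^2}}, so
#' \deqn{z = \frac{2(se_1 + se_2)}{\sqrt{se_1^2 + se_2^2}}}
#' and the two-sided normal tail of `z` bounds the p-value of any
#' difference at least that large. Note `z` ranges between 2 and
#' \eqn{2\sqrt 2}, so touching CIs always satisfy p < 0.05.
#'
#' @param se1,se2 Non-negative standard errors, not both zero.
#' @return An object of class `ci_comparison`: `se1`, `se2`, `z`, `p`
#'   (two-sided) and `significant` (p < 0.05).
#' @export
ci_significance <- function(se1, se2) {
  stopifnot(is.numeric(se1), is.numeric(se2), se1 >= 0, se2 >= 0)
  if (se1 == 0 && se2 == 0) stop("both standard errors are zero")
  z <- 2 * (se1 + se2) / sqrt(se1^2 + se2^2)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(se1 = se1, se2 = se2, z = z, p = p, significant = p < 0.05),
            class = "ci_comparison")
}

#' @export
print.ci_comparison <- function(x, ...) {
  cat(sprintf("z = %.4f, p = %.4g (%ssignificant)\n", x$z, x$p,
              if (x$significant) "" else "not "))
  invisible(x)
}

# Do two intervals overlap (touching counts as non-overlapping under the
# CI rule: a touching or disjoint pair is declared significant)?
cis_disjoint_or_touching <- function(lo1, hi1, lo2, hi2) {
  hi1 <= lo2 | hi2 <= lo1
}

#' Per-predictor performance over a call matrix
#'
#' Convenience wrapper computing [confusion_counts()] and
#' [performance_stats()] for every predictor column, optionally with
#' bootstrap CIs.
#'
#' @param matrix A [call_matrix()].
#' @param bootstrap `NULL`, or a list with `iterations` and `seed` to
#'   attach bootstrap CIs (the labelled variants are resampled).
#' @return Named list of `performance_stats`, one per predictor.
#' @export
panel_performance <- function(matrix, bootstrap = NULL) {
  stopifnot(inherits(matrix, "call_matrix"))
  truth <- matrix$variants$truth_label
  stats::setNames(lapply(colnames(matrix$calls), function(nm) {
    calls <- matrix$calls[, nm]
    counts <- confusion_counts(calls, truth)
    bs <- NULL
    if (!is.null(bootstrap)) {
      keep <- truth %in% TRUTH_LEVELS[1:2]
      bs <- list(calls = calls[keep], truth = truth[keep],
                 iterations = bootstrap$iterations, seed = bootstrap$seed)
    }
    performance_stats(counts, bs)
  }), colnames(matrix$calls))
}

#' Median and range of each metric over a predictor panel
#'
#' @param stats_list A (named) list of [performance_stats()] objects.
#' @return A data frame with one row per metric: `median`, `min`, `max`.
#'   The five proportion metrics are reported on the percentage scale;
#'   the composite score on its native 0-4 scale.
#' @export
cohort_summary <- function(stats_list) {
  stopifnot(length(stats_list) >= 1L)
  rows <- lapply(METRIC_NAMES, function(nm) {
    vals <- vapply(stats_list, `[[`, numeric(1), nm)
    if (nm != "composite") vals <- 100 * vals
    data.frame(metric = nm, median = stats::median(vals),
               min = min(vals), max = max(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Performance restricted to a stratum of variants
#'
#' Recomputes per-predictor performance on the subset of variants
#' selected by `stratum`, e.g. only oncogene variants or only variants
#' absent from COSMIC.
#'
#' @param matrix A [call_matrix()].
#' @param stratum Either a logical vector over variants or a predicate
#'   `function(variants_df)` returning one; it must select at least one
#'   labelled variant.
#' @param bootstrap As in [panel_performance()].
#' @return Named list of `performance_stats`.
#' @export
stratified_performance <- function(matrix, stratum, bootstrap = NULL) {
  stopifnot(inherits(matrix, "call_matrix"))
  sel <- if (is.function(stratum)) stratum(matrix$variants) else stratum
  stopifnot(is.logical(sel), length(sel) == nrow(matrix$variants))
  sel <- sel & !is.na(sel)
  if (!any(sel & matrix$variants$truth_label %in% TRUTH_LEVELS[1:2])) {
    stop("stratum selects no labelled variants")
  }
  sub <- call_matrix(matrix$variants[sel, , drop = FALSE],
                     matrix$calls[sel, , drop = FALSE],
                     mode = matrix$mode, specs = matrix$specs)
  panel_performance(sub, bootstrap = bootstrap)
}

#' Flatten panel performance into a report table
#'
#' @param stats_list Named list of [performance_stats()].
#' @return A data frame with one row per predictor; proportion metrics on
#'   the percentage scale, composite on 0-4, plus CI columns when
#'   available. Suitable for [write_table()].
#' @export
performance_table <- function(stats_list) {
  rows <- lapply(names(stats_list), function(nm) {
    s <- stats_list[[nm]]
    row <- data.frame(predictor = nm, stringsAsFactors = FALSE)
    for (m in METRIC_NAMES) {
      scale <- if (m == "composite") 1 else 100
      row[[m]] <- scale * s[[m]]
      if (!is.null(s$ci)) {
        row[[paste0(m, "_lo")]] <- scale * s$ci[[m]][1]
        row[[paste0(m, "_hi")]] <- scale * s$ci[[m]][2]
      }
    }
    row
  })
  do.call(rbind, rows)
}
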
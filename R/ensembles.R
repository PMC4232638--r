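#' Enumerate n-of-p voting rules over a predictor panel
#'
#' A voting rule is a subset of `n` single predictors together with a
#' vote threshold `p` (1 <= p <= n): a variant is called non-neutral when
#' at least `p` members call it non-neutral. All `(members, p)` pairs
#' with subset sizes from `n_min` to the panel size are enumerated; for
#' `n_min = 2` over `N` predictors this yields
#' \eqn{N \cdot 2^{N-1} - N} distinct rules (11,253 for `N = 11`).
#'
#' @param predictors Character vector of (unique) single-predictor names.
#' @param n_min Smallest subset size (default 2; use 1 to include
#'   singleton baselines).
#' @return A data frame of class `ensemble_rules` with columns `rule_id`,
#'   `members` (list column), `members_str` (members joined by `" + "`),
#'   `set_id` (index of the member subset), `n` and `p`.
#' @export
enumerate_rules <- function(predictors, n_min = 2L) {
  if (anyDuplicated(predictors)) stop("duplicate predictor names")
  N <- length(predictors)
  if (N < 1L || N < n_min) stop("need at least ", max(1L, n_min), " predictors")
  sets <- list()
  for (n in seq(n_min, N)) {
    combos <- utils::combn(predictors, n, simplify = FALSE)
    sets <- c(sets, combos)
  }
  sizes <- lengths(sets)
  reps <- sizes  # one rule per threshold p = 1..n
  members <- rep(sets, times = reps)
  set_id <- rep(seq_along(sets), times = reps)
  p <- unlist(lapply(sizes, seq_len))
  members_str <- vapply(members, paste, "", collapse = " + ")
  out <- data.frame(
    rule_id = sprintf("%s | p>=%d", members_str, p),
    members_str = members_str,
    set_id = set_id,
    n = rep(sizes, times = reps),
    p = p,
    stringsAsFactors = FALSE
  )
  out$members <- members
  class(out) <- c("ensemble_rules", "data.frame")
  attr(out, "member_sets") <- sets
  out
}

#' Singleton baseline rules
#'
#' One `n = 1, p = 1` rule per predictor, used to evaluate individual
#' predictors under the same split-sample machinery as the ensembles.
#'
#' @param predictors Character vector of predictor names.
#' @return An `ensemble_rules` data frame.
#' @export
singleton_rules <- function(predictors) {
  rules <- enumerate_rules(predictors, n_min = 1L)
  out <- rules[rules$n == 1L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ensemble_rules", "data.frame")
  out
}

#' Apply a voting rule to a call matrix
#'
#' Counts, per variant, how many member predictors called it non-neutral
#' and returns `non_neutral` when the count reaches the threshold `p`,
#' else `neutral`. Equivocal (and low-confidence) member calls contribute
#' no vote but keep the denominator at `n`; the ensemble output is never
#' equivocal.
#'
#' @param rule A list (or one-row `ensemble_rules` slice) with `members`
#'   and `p`.
#' @param matrix A [call_matrix()].
#' @return Character call vector over the matrix's variants.
#' @export
apply_rule <- function(rule, matrix) {
  stopifnot(inherits(matrix, "call_matrix"))
  members <- if (is.list(rule$members) && !is.character(rule$members)) {
    rule$members[[1L]]
  } else {
    rule$members
  }
  p <- rule$p
  missing_m <- setdiff(members, colnames(matrix$calls))
  if (length(missing_m)) {
    stop("call matrix lacks member(s): ", paste(missing_m, collapse = ", "))
  }
  votes <- rowSums(matrix$calls[, members, drop = FALSE] == "non_neutral")
  unname(ifelse(votes >= p, "non_neutral", "neutral"))
}

#' Split-sample configuration
#'
#' @param fraction_subset1 Fraction of the labelled variants assigned to
#'   subset 1 (default 2/3; subset sizes use round-half-up, so 989
#'   variants split 659/330).
#' @param repetitions Number of random splits (default 1000).
#' @param seed Base RNG seed; each repetition derives its own stream so
#'   splits are reproducible individually.
#' @param stratified Stratify the split by truth label? Defaults to
#'   `FALSE` (a plain random split).
#' @return A list of class `split_config`.
#' @export
split_config <- function(fraction_subset1 = 2 / 3, repetitions = 1000L,
                         seed = 1L, stratified = FALSE) {
  stopifnot(fraction_subset1 > 0, fraction_subset1 < 1, repetitions >= 1L)
  structure(list(fraction_subset1 = fraction_subset1,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), stratified = stratified),
            class = "split_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Split labelled variants into two subsets
#'
#' Randomly partitions the variants into subset 1 (of size
#' `round(fraction * n)`, half-up) and subset 2 (the rest). The split is
#' deterministic given `(config$seed, iteration)`.
#'
#' @param variants A data frame with `variant_id` and `truth_label`
#'   columns (a character vector of ids is accepted when the split is
#'   unstratified).
#' @param config A [split_config()].
#' @param iteration Repetition index (>= 1).
#' @return A list with `subset1` and `subset2`, character vectors of
#'   variant ids.
#' @export
split_dataset <- function(variants, config, iteration = 1L) {
  stopifnot(inherits(config, "split_config"))
  if (is.character(variants)) {
    variants <- data.frame(variant_id = variants,
                           truth_label = NA_character_,
                           stringsAsFactors = FALSE)
  }
  ids <- variants$variant_id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 labelled variants to split")
  idx1 <- with_seed(derive_seed(config$seed, iteration), {
    if (config$stratified) {
      strata <- split(seq_len(n), variants$truth_label)
      unlist(lapply(strata, function(s) {
        k <- round_half_up(config$fraction_subset1 * length(s))
        sample(s, k)
      }), use.names = FALSE)
    } else {
      sample.int(n, round_half_up(config$fraction_subset1 * n))
    }
  })
  if (length(idx1) == 0L || length(idx1) == n) {
    stop("degenerate split: one subset is empty")
  }
  list(subset1 = ids[sort(idx1)], subset2 = ids[-sort(idx1)])
}

# Internal vectorised evaluation core. For all rules at once:
# votes = I(call == non_neutral) %*% membership, computed once; for each
# repetition and subset, tp/fp per (member set, p) follow from column
# sums of vote-threshold indicators over the truth strata.
evaluate_splits_core <- function(rules, calls, truth, config) {
  usets <- unique(rules$set_id)
  sets <- rules$members[match(usets, rules$set_id)]
  set_col <- match(rules$set_id, usets)
  preds <- unique(unlist(sets))
  missing_m <- setdiff(preds, colnames(calls))
  if (length(missing_m)) {
    stop("call matrix lacks member(s): ", paste(missing_m, collapse = ", "))
  }
  labelled <- truth %in% TRUTH_LEVELS[1:2]
  calls <- calls[labelled, , drop = FALSE]
  truth <- truth[labelled]
  n_var <- nrow(calls)
  if (n_var < 2L) stop("need at least 2 labelled variants")

  NN <- (calls[, preds, drop = FALSE] == "non_neutral") * 1L
  M <- vapply(sets, function(s) as.integer(preds %in% s),
              integer(length(preds)))
  votes <- NN %*% M  # n_var x n_sets
  is_nn <- truth == "non_neutral"
  max_p <- max(rules$p)
  n_rules <- nrow(rules)
  reps <- config$repetitions
  rule_cell <- cbind(rules$p, set_col)

  res <- lapply(1:2, function(s) {
    lapply(METRIC_NAMES, function(m) {
      base::matrix(NA_real_, n_rules, reps)
    }) |> stats::setNames(METRIC_NAMES)
  })

  vdf <- data.frame(variant_id = rownames(calls) %||% as.character(seq_len(n_var)),
                    truth_label = truth, stringsAsFactors = FALSE)
  row_index <- stats::setNames(seq_len(n_var), vdf$variant_id)

  for (it in seq_len(reps)) {
    sp <- split_dataset(vdf, config, it)
    for (s in 1:2) {
      rows <- row_index[sp[[s]]]
      v_nn <- votes[rows[is_nn[rows]], , drop = FALSE]
      v_ne <- votes[rows[!is_nn[rows]], , drop = FALSE]
      n_nn <- nrow(v_nn)
      n_ne <- nrow(v_ne)
      tp_mat <- base::matrix(0, max_p, ncol(votes))
      fp_mat <- base::matrix(0, max_p, ncol(votes))
      for (p in seq_len(max_p)) {
        tp_mat[p, ] <- colSums(v_nn >= p)
        fp_mat[p, ] <- colSums(v_ne >= p)
      }
      tp <- tp_mat[rule_cell]
      fp <- fp_mat[rule_cell]
      tn <- n_ne - fp
      fn <- n_nn - tp
      m <- metrics_from_counts(tp, fp, tn, fn)
      for (nm in METRIC_NAMES) res[[s]][[nm]][, it] <- m[[nm]]
    }
  }
  res
}

#' Evaluate voting rules over repeated split samples
#'
#' Repeats the random split `config$repetitions` times and, for each
#' rule and each subset, records the mean, percentile 95% CI and
#' standard deviation of every performance metric across the
#' repetitions. Only labelled (non-uncertain) variants are used. The
#' entire computation is vectorised over rules and deterministic for a
#' fixed `config$seed`.
#'
#' @param rules An [enumerate_rules()] data frame (singletons from
#'   [singleton_rules()] are allowed).
#' @param matrix A [call_matrix()].
#' @param truth Optional truth-label vector; defaults to the matrix's
#'   variant records.
#' @param config A [split_config()].
#' @return A data frame of class `rule_evaluation` with one row per
#'   (rule, subset): rule identifiers, `subset` (1 or 2) and, for each
#'   metric, `<metric>_mean`, `<metric>_lo`, `<metric>_hi`,
#'   `<metric>_sd`. Proportion metrics are on the 0-1 scale.
#' @export
evaluate_over_splits <- function(rules, matrix, truth = NULL,
                                 config = split_config()) {
  stopifnot(inherits(matrix, "call_matrix"), nrow(rules) >= 1L)
  truth <- truth %||% matrix$variants$truth_label
  res <- evaluate_splits_core(rules, matrix$calls, truth, config)
  alpha <- 0.025
  out <- lapply(1:2, function(s) {
    df <- data.frame(rule_id = rules$rule_id, members_str = rules$members_str,
                     n = rules$n, p = rules$p, subset = s,
                     stringsAsFactors = FALSE)
    for (nm in METRIC_NAMES) {
      x <- res[[s]][[nm]]
      df[[paste0(nm, "_mean")]] <- rowMeans(x)
      qs <- apply(x, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                  names = FALSE)
      df[[paste0(nm, "_lo")]] <- qs[1, ]
      df[[paste0(nm, "_hi")]] <- qs[2, ]
      df[[paste0(nm, "_sd")]] <- apply(x, 1, stats::sd)
    }
    df
  })
  out <- rbind(out[[1]], out[[2]])
  out$members <- rep(rules$members, 2L)
  class(out) <- c("rule_evaluation", "data.frame")
  attr(out, "config") <- config
  out
}

#' Rank evaluated rules and flag improvements over baselines
#'
#' Ranks rules within each subset by mean accuracy and by mean composite
#' score (ties broken by the other criterion, then by member names).
#' When baselines are supplied, each rule is flagged for (a) a
#' numerically higher mean than the baseline in both subsets and (b) a
#' significant improvement -- a higher mean with across-repetition 95%
#' CIs that touch or do not overlap -- in both subsets.
#'
#' @param evaluations A [evaluate_over_splits()] result.
#' @param by Primary ranking criterion: `"accuracy"` or `"composite"`.
#' @param baselines Optional named list of baseline rows (e.g.
#'   `list(single = <row>, meta = <row>)`), each a one-rule slice of a
#'   `rule_evaluation` covering both subsets.
#' @param metric Metric used for the baseline comparison flags (default:
#'   the ranking criterion). Improvements in e.g. `"npv"` can be flagged
#'   while still ranking by accuracy.
#' @return A data frame of class `ranked_rules`: one row per rule with
#'   per-subset means, `rank_by_accuracy_s1/s2`, `rank_by_composite_s1/s2`
#'   and, per baseline `<name>`, `beats_<name>_both` and
#'   `sig_<name>_s1`/`sig_<name>_s2`/`sig_<name>_both`. Rows are ordered
#'   by the subset-1 ranking under `by`.
#' @export
rank_rules <- function(evaluations, by = c("accuracy", "composite"),
                       baselines = NULL, metric = NULL) {
  by <- match.arg(by)
  metric <- metric %||% by
  stopifnot(inherits(evaluations, "rule_evaluation"))
  e1 <- evaluations[evaluations$subset == 1, , drop = FALSE]
  e2 <- evaluations[evaluations$subset == 2, , drop = FALSE]
  stopifnot(identical(e1$rule_id, e2$rule_id))
  out <- data.frame(rule_id = e1$rule_id, members_str = e1$members_str,
                    n = e1$n, p = e1$p, stringsAsFactors = FALSE)
  for (nm in METRIC_NAMES) {
    out[[paste0(nm, "_s1")]] <- e1[[paste0(nm, "_mean")]]
    out[[paste0(nm, "_s2")]] <- e2[[paste0(nm, "_mean")]]
  }
  rank_of <- function(vals, tie_vals, names) {
    ord <- order(-vals, -tie_vals, names, method = "radix")
    r <- integer(length(vals))
    r[ord] <- seq_along(vals)
    r
  }
  other <- if (by == "accuracy") "composite" else "accuracy"
  out$rank_by_accuracy_s1 <- rank_of(out$accuracy_s1, out$composite_s1,
                                     out$members_str)
  out$rank_by_accuracy_s2 <- rank_of(out$accuracy_s2, out$composite_s2,
                                     out$members_str)
  out$rank_by_composite_s1 <- rank_of(out$composite_s1, out$accuracy_s1,
                                      out$members_str)
  out$rank_by_composite_s2 <- rank_of(out$composite_s2, out$accuracy_s2,
                                      out$members_str)
  if (!is.null(baselines)) {
    for (bn in names(baselines)) {
      b <- baselines[[bn]]
      b1 <- b[b$subset == 1, , drop = FALSE]
      b2 <- b[b$subset == 2, , drop = FALSE]
      mcol <- function(d, suffix) d[[paste0(metric, suffix)]]
      higher1 <- mcol(e1, "_mean") > mcol(b1, "_mean")
      higher2 <- mcol(e2, "_mean") > mcol(b2, "_mean")
      sig1 <- higher1 & cis_disjoint_or_touching(
        mcol(e1, "_lo"), mcol(e1, "_hi"), mcol(b1, "_lo"), mcol(b1, "_hi"))
      sig2 <- higher2 & cis_disjoint_or_touching(
        mcol(e2, "_lo"), mcol(e2, "_hi"), mcol(b2, "_lo"), mcol(b2, "_hi"))
      out[[paste0("beats_", bn, "_both")]] <- higher1 & higher2
      out[[paste0("sig_", bn, "_s1")]] <- sig1
      out[[paste0("sig_", bn, "_s2")]] <- sig2
      out[[paste0("sig_", bn, "_both")]] <- sig1 & sig2
    }
  }
  out$members <- e1$members
  out <- out[order(out[[paste0("rank_by_", by, "_s1")]]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_rules", "data.frame")
  attr(out, "by") <- by
  attr(out, "metric") <- metric
  out
}

#' Recurrence of single predictors in the top-ranked rules
#'
#' For each predictor, counts how many of the top `k` rules (per subset
#' and per ranking criterion) contain it.
#'
#' @param ranked A [rank_rules()] result.
#' @param k Number of top rules to inspect (must not exceed the number of
#'   rules); typical values are 10, 20, 50, 100.
#' @return A data frame with columns `predictor`, `criterion`
#'   (`accuracy`/`composite`), `subset`, `k` and `count` (bounded by `k`).
#' @export
recurrence_in_top <- function(ranked, k) {
  stopifnot(inherits(ranked, "ranked_rules"))
  if (k > nrow(ranked)) stop("k exceeds the number of rules")
  preds <- sort(unique(unlist(ranked$members)))
  rows <- list()
  for (crit in c("accuracy", "composite")) {
    for (s in 1:2) {
      rk <- ranked[[paste0("rank_by_", crit, "_s", s)]]
      top_members <- ranked$members[rk <= k]
      counts <- table(factor(unlist(top_members), levels = preds))
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = preds, criterion = crit, subset = s, k = k,
        count = as.integer(counts), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Mean accuracy across the (n, p) rule grid
#'
#' Summarises, per subset, the mean and maximum of mean accuracy over all
#' rules sharing a given panel size `n` and vote threshold `p`, to locate
#' the best-performing region of the voting-rule space. Cells with
#' `p > n` do not exist.
#'
#' @param evaluations A [evaluate_over_splits()] result.
#' @return A data frame with columns `subset`, `n`, `p`, `n_rules`,
#'   `mean_accuracy`, `max_accuracy` and `best_members` (the member set
#'   achieving the maximum).
#' @export
np_grid_summary <- function(evaluations) {
  stopifnot(inherits(evaluations, "rule_evaluation"))
  keys <- interaction(evaluations$subset, evaluations$n, evaluations$p,
                      drop = TRUE)
  rows <- lapply(split(seq_len(nrow(evaluations)), keys), function(idx) {
    e <- evaluations[idx, , drop = FALSE]
    best <- which.max(e$accuracy_mean)
    data.frame(subset = e$subset[1], n = e$n[1], p = e$p[1],
               n_rules = nrow(e),
               mean_accuracy = mean(e$accuracy_mean),
               max_accuracy = e$accuracy_mean[best],
               best_members = e$members_str[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subset, out$n, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
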
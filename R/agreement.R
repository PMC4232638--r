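#' Unweighted Cohen's kappa between two call vectors
#'
#' Agreement is computed over the variants where both raters made a
#' definite call (`non_neutral` or `neutral`); pairs involving an
#' equivocal or low-confidence call are dropped and the number of variants
#' actually compared is reported as `n_used`. Kappa is
#' \eqn{(p_o - p_e) / (1 - p_e)} with observed agreement \eqn{p_o} and
#' chance agreement \eqn{p_e} from the marginal call frequencies; when
#' both raters are constant and identical (\eqn{p_e = 1}, \eqn{p_o = 1})
#' kappa is defined as 1.
#'
#' The optional confidence interval is a percentile bootstrap over the
#' compared variants, the same resampling machinery used for the
#' performance metrics.
#'
#' @param calls_a,calls_b Character call vectors of equal length.
#' @param ci Compute a bootstrap confidence interval?
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `kappa_result`: list with `kappa`,
#'   `ci_low`, `ci_high` (NA unless `ci = TRUE`), `n_used` and the
#'   qualitative agreement `band` (see [interpret_kappa()]).
#' @examples
#' a <- c("non_neutral", "neutral", "non_neutral", "neutral")
#' cohen_kappa(a, a)$kappa  # 1
#' @export
cohen_kappa <- function(calls_a, calls_b, ci = FALSE, iterations = 1000L,
                        seed = 1L, conf_level = 0.95) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length")
  }
  if (length(calls_a) < 2L) stop("need at least 2 variants")
  keep <- calls_a %in% CALL_LEVELS[1:2] & calls_b %in% CALL_LEVELS[1:2]
  if (!any(keep)) stop("no variant has a definite call from both raters")
  a <- calls_a[keep]
  b <- calls_b[keep]
  k <- kappa_value(a, b)
  ci_low <- ci_high <- NA_real_
  if (ci) {
    n <- length(a)
    draws <- with_seed(seed, vapply(seq_len(iterations), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      kappa_value(a[idx], b[idx])
    }, numeric(1)))
    alpha <- (1 - conf_level) / 2
    qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE,
                          na.rm = TRUE)
    ci_low <- qs[1]
    ci_high <- qs[2]
  }
  structure(
    list(kappa = k, ci_low = ci_low, ci_high = ci_high,
         n_used = length(a), band = interpret_kappa(k)),
    class = "kappa_result"
  )
}

# Point estimate of unweighted kappa on definite-call vectors.
kappa_value <- function(a, b) {
  n <- length(a)
  fa <- factor(a, levels = CALL_LEVELS[1:2])
  fb <- factor(b, levels = CALL_LEVELS[1:2])
  tab <- table(fa, fb)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    # Both raters constant: perfect agreement iff they agree everywhere.
    return(if (p_o >= 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa = %.4f (%s agreement), n_used = %d\n",
              x$kappa, gsub("_", " ", x$band), x$n_used))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI: %.4f - %.4f\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Qualitative interpretation of a kappa coefficient
#'
#' Conventional agreement bands: kappa below 0 is no agreement,
#' 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial and 0.81-1 almost perfect agreement.
#'
#' @param kappa A number in \[-1, 1\].
#' @return One of `"no"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost_perfect"`.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L)
  if (is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]")
  }
  if (kappa < 0) "no"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost_perfect"
}

#' Pairwise kappa matrix across a predictor panel
#'
#' Computes unweighted Cohen's kappa for every pair of predictors in a
#' call matrix. The diagonal is 1 by definition. When `groups` is given
#' (a named vector mapping predictor names to group labels), the result
#' additionally summarises the median and range of kappa within each
#' group and between each pair of groups.
#'
#' @param matrix A [call_matrix()].
#' @param groups Optional named character/factor vector of group labels.
#' @return A list with `kappa` (symmetric numeric matrix), `n_used`
#'   (variants compared per pair) and `group_summary` (data frame or
#'   `NULL`).
#' @export
pairwise_kappa_matrix <- function(matrix, groups = NULL) {
  stopifnot(inherits(matrix, "call_matrix"))
  preds <- colnames(matrix$calls)
  p <- length(preds)
  if (p < 2L) stop("need at least 2 predictors")
  km <- diag(1, p)
  nm <- base::matrix(nrow(matrix$calls), p, p)
  dimnames(km) <- dimnames(nm) <- list(preds, preds)
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      res <- cohen_kappa(matrix$calls[, i], matrix$calls[, j])
      km[i, j] <- km[j, i] <- res$kappa
      nm[i, j] <- nm[j, i] <- res$n_used
    }
  }
  group_summary <- NULL
  if (!is.null(groups)) {
    if (!all(preds %in% names(groups))) {
      stop("groups must label every predictor")
    }
    g <- as.character(groups[preds])
    labs <- unique(g)
    rows <- list()
    for (gi in seq_along(labs)) {
      for (gj in seq(gi, length(labs))) {
        ii <- which(g == labs[gi])
        jj <- which(g == labs[gj])
        if (gi == gj) {
          if (length(ii) < 2L) next
          vals <- km[ii, ii][upper.tri(km[ii, ii])]
          label <- paste0("within ", labs[gi])
        } else {
          vals <- as.vector(km[ii, jj, drop = FALSE])
          label <- paste0(labs[gi], " vs ", labs[gj])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = label, n_pairs = length(vals),
          median_kappa = stats::median(vals),
          min_kappa = min(vals), max_kappa = max(vals),
          stringsAsFactors = FALSE
        )
      }
    }
    group_summary <- do.call(rbind, rows)
  }
  list(kappa = km, n_used = nm, group_summary = group_summary)
}

#' Hamming distance between two call vectors
#'
#' The fraction of positions whose call symbols differ. Every call
#' category is its own symbol: an equivocal (or low-confidence) call
#' mismatches anything except another call of the same category, so no
#' variants are dropped.
#'
#' @param calls_a,calls_b Character call vectors of equal length >= 1.
#' @return A number in \[0, 1\].
#' @export
hamming_distance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length")
  }
  if (length(calls_a) < 1L) stop("need at least 1 position")
  mean(calls_a != calls_b)
}

#' Cluster predictors by call similarity
#'
#' Hierarchical clustering of the predictor panel with complete linkage
#' on pairwise Hamming distances between harmonized call vectors. For a
#' fixed input column order the result is deterministic (ties between
#' equal merge distances are resolved by column order). Complete linkage
#' guarantees non-decreasing merge heights.
#'
#' @param matrix A [call_matrix()] with at least 2 predictors.
#' @return An object of class `predictor_dendrogram`: a list with `hclust`
#'   (the merge tree), `dist` (the pairwise distance matrix as `dist`)
#'   and `newick` (the tree serialised as a Newick string with merge
#'   heights converted to branch lengths).
#' @export
cluster_predictors <- function(matrix) {
  stopifnot(inherits(matrix, "call_matrix"))
  preds <- colnames(matrix$calls)
  p <- length(preds)
  if (p < 2L) stop("need at least 2 predictors")
  dm <- base::matrix(0, p, p, dimnames = list(preds, preds))
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      dm[i, j] <- dm[j, i] <-
        hamming_distance(matrix$calls[, i], matrix$calls[, j])
    }
  }
  d <- stats::as.dist(dm)
  hc <- stats::hclust(d, method = "complete")
  phy <- ape::as.phylo(hc)
  structure(
    list(hclust = hc, dist = d, phylo = phy,
         newick = ape::write.tree(phy)),
    class = "predictor_dendrogram"
  )
}

#' @export
print.predictor_dendrogram <- function(x, ...) {
  cat("predictor_dendrogram over", length(x$hclust$labels), "predictors\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Cut a predictor dendrogram into k clusters
#'
#' @param dendrogram A [cluster_predictors()] result.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_predictor_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "predictor_dendrogram"))
  stats::cutree(dendrogram$hclust, k = k)
}

#' Export a pairwise kappa matrix as a TSV table
#'
#' Writes one row per predictor pair with the kappa value (4 decimal
#' places) and the number of variants compared.
#'
#' @param km A [pairwise_kappa_matrix()] result.
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_kappa_table <- function(km, path) {
  preds <- rownames(km$kappa)
  idx <- which(upper.tri(km$kappa), arr.ind = TRUE)
  df <- data.frame(
    predictor_a = preds[idx[, 1]],
    predictor_b = preds[idx[, 2]],
    kappa = km$kappa[idx],
    n_used = as.integer(km$n_used[idx]),
    band = vapply(km$kappa[idx], interpret_kappa, ""),
    stringsAsFactors = FALSE
  )
  write_table(df, path)
  invisible(df)
}
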
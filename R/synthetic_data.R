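#' Configuration for a synthetic rater-panel simulation
#'
#' Describes a cohort of SNVs and a panel of raters (synthetic
#' predictors) with known operating characteristics. The default cohort
#' composition (849 non-neutral, 140 neutral, 2,602 uncertain) matches
#' the benchmark truth-set the package's regression fixtures are built
#' on.
#'
#' Correlated rater errors are induced by a Gaussian one-factor copula
#' per cluster: each variant carries one latent standard-normal factor
#' per rater cluster, and rater `j` in cluster `c` forms its correctness
#' indicator by thresholding
#' \eqn{\sqrt{\rho}\, Z_c + \sqrt{1-\rho}\,\epsilon_j} so that its
#' marginal correctness equals its configured sensitivity (on
#' non-neutral variants) or specificity (on neutral variants). Raters in
#' different clusters err independently.
#'
#' @param raters A data frame with columns `name`, `kind`
#'   (`single`/`meta`), `sensitivity`, `specificity`, `equivocal_rate`
#'   and `cluster_id`.
#' @param n_non_neutral,n_neutral,n_uncertain Cohort composition.
#' @param cluster_correlation Within-cluster latent correlation
#'   \eqn{\rho} in \[0, 1).
#' @param positive_rate Probability that a rater calls a truth-uncertain
#'   variant non-neutral. Default `NULL`: the panel's mean positive call
#'   rate on labelled variants,
#'   mean over raters of (sens * n_nn + (1 - spec) * n_ne) / (n_nn + n_ne).
#' @param gene_class_probs Marginal probabilities of the three gene
#'   classes (oncogene / TSG / new cancer gene).
#' @param cosmic_prob Marginal probability that a variant is in COSMIC.
#' @param seed Base RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(raters,
                              n_non_neutral = 849L, n_neutral = 140L,
                              n_uncertain = 2602L,
                              cluster_correlation = 0.6,
                              positive_rate = NULL,
                              gene_class_probs = c(oncogene = 0.147,
                                                   tsg = 0.794,
                                                   new_cancer_gene = 0.059),
                              cosmic_prob = 0.527,
                              seed = 1L) {
  stopifnot(is.data.frame(raters),
            all(c("name", "kind", "sensitivity", "specificity",
                  "equivocal_rate", "cluster_id") %in% names(raters)))
  rates <- c(raters$sensitivity, raters$specificity, raters$equivocal_rate)
  if (any(rates < 0 | rates > 1)) stop("rater rates must lie in [0, 1]")
  if (anyDuplicated(raters$name)) stop("duplicate rater names")
  stopifnot(n_non_neutral >= 0, n_neutral >= 0, n_uncertain >= 0,
            cluster_correlation >= 0, cluster_correlation < 1)
  if (n_non_neutral + n_neutral + n_uncertain == 0L) {
    stop("cohort is empty")
  }
  if (is.null(positive_rate)) {
    n_lab <- n_non_neutral + n_neutral
    positive_rate <- if (n_lab > 0) {
      mean((raters$sensitivity * n_non_neutral +
              (1 - raters$specificity) * n_neutral) / n_lab)
    } else 0.5
  }
  structure(
    list(raters = raters, n_non_neutral = as.integer(n_non_neutral),
         n_neutral = as.integer(n_neutral),
         n_uncertain = as.integer(n_uncertain),
         cluster_correlation = cluster_correlation,
         positive_rate = positive_rate,
         gene_class_probs = gene_class_probs, cosmic_prob = cosmic_prob,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' A benchmark-like 15-rater panel
#'
#' Returns the default rater panel used by the package's end-to-end
#' simulations: 11 single raters and 4 meta raters named after the
#' predictors of the reference benchmark, with per-rater sensitivity and
#' specificity set to the values those predictors achieved on the
#' validated truth set, equivocal rates matching each predictor's
#' no-call/N-A frequency, and a two-cluster-plus-outlier agreement
#' structure (the cancer-specific predictors and the consensus tools in
#' one cluster, the conservation-based general predictors in the other,
#' with one tissue-mismatched outlier).
#'
#' @return A data frame suitable for [simulation_config()].
#' @export
benchmark_raters <- function() {
  data.frame(
    name = c("CHASM (breast)", "CHASM (lung)", "CHASM (melanoma)",
             "FATHMM (cancer)", "FATHMM (missense)", "Condel",
             "CanDrA (lung)", "CanDrA (melanoma)",
             "Mutation Assessor", "MutationTaster", "PolyPhen-2",
             "PROVEAN", "SIFT", "VEST", "CanDrA (breast)"),
    kind = c("single", "single", "single", "single", "single", "meta",
             "meta", "meta",
             "single", "single", "single", "single", "single", "single",
             "meta"),
    sensitivity = c(0.8999, 0.9223, 0.9364, 0.9788, 0.8775, 0.9258,
                    0.9286, 0.9073,
                    0.7665, 0.9081, 0.8422, 0.7444, 0.8610, 0.8269,
                    0.9538),
    specificity = c(0.8071, 0.7714, 0.6571, 0.4929, 0.5071, 0.4500,
                    0.8095, 0.7760,
                    0.6286, 0.7500, 0.5286, 0.6929, 0.5000, 0.2857,
                    0.0000),
    equivocal_rate = c(0, 0, 0, 0, 19 / 3591, 0,
                       207 / 3591, 250 / 3591,
                       7 / 3591, 0, 0, 0, 0, 0,
                       44 / 3591),
    cluster_id = c(rep("cluster1", 8L), rep("cluster2", 6L), "outlier"),
    stringsAsFactors = FALSE
  )
}

#' Identity specs for synthetic raters
#'
#' Synthetic raters emit raw categories that are already in the
#' harmonized vocabulary; their [predictor_spec()] is therefore an
#' identity category map. Use these specs to run simulated panels
#' through [build_call_matrix()] and the downstream analyses.
#'
#' @param raters A rater data frame (see [simulation_config()]) or a
#'   character vector of rater names (all treated as `single`).
#' @return A named list of [predictor_spec()] objects.
#' @export
synthetic_rater_specs <- function(raters) {
  if (is.character(raters)) {
    raters <- data.frame(name = raters, kind = "single",
                         stringsAsFactors = FALSE)
  }
  id_map <- c("non_neutral" = "non_neutral", "neutral" = "neutral",
              "equivocal" = "equivocal")
  stats::setNames(lapply(seq_len(nrow(raters)), function(i) {
    predictor_spec(raters$name[i], raters$kind[i], id_map)
  }), raters$name)
}

#' Simulate variant records with configured truth-label composition
#'
#' Generates exactly the configured numbers of non-neutral, neutral and
#' uncertain variant records; genes, gene classes and COSMIC membership
#' are drawn from the configured marginal proportions. Deterministic for
#' a fixed `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A variant record data frame (see [raw_call_table()]).
#' @export
simulate_truth_labels <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- rep(TRUTH_LEVELS,
                c(config$n_non_neutral, config$n_neutral, config$n_uncertain))
  n <- length(labels)
  genes_by_class <- list(
    oncogene = c("BRAF", "KIT", "PIK3CA", "KRAS", "EGFR", "ERBB2"),
    tsg = c("TP53", "BRCA1", "BRCA2"),
    new_cancer_gene = c("ESR1", "DICER1", "MYOD1", "IDH1", "IDH2", "SF3B1")
  )
  with_seed(derive_seed(config$seed, 1L), {
    gene_class <- sample(names(config$gene_class_probs), n, replace = TRUE,
                         prob = config$gene_class_probs)
    gene <- vapply(gene_class,
                   function(gc) sample(genes_by_class[[gc]], 1L), "")
    aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
    data.frame(
      variant_id = sprintf("%s:p.%s%d%s", gene,
                           sample(aa, n, TRUE), seq_len(n), sample(aa, n, TRUE)),
      gene = gene,
      gene_class = gene_class,
      truth_label = labels,
      in_cosmic = stats::runif(n) < config$cosmic_prob,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a correlated panel of rater calls
#'
#' Produces a [raw_call_table()] whose raw categories are already in the
#' harmonized vocabulary (`non_neutral` / `neutral` / `equivocal`), as
#' produced by raters with the configured sensitivity, specificity and
#' equivocal rate and the cluster-correlated error structure described
#' in [simulation_config()]. Truth-uncertain variants receive
#' non-neutral calls at the configured `positive_rate`. Equivocal calls
#' are injected independently per rater at `equivocal_rate`.
#'
#' @param truth Variant records from [simulate_truth_labels()].
#' @param config A [simulation_config()].
#' @return A `raw_call_table` (scores all `NA`; see [simulate_scores()]).
#' @export
simulate_call_matrix <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(truth))
  raters <- config$raters
  if (!nrow(raters)) stop("rater panel is empty")
  n <- nrow(truth)
  rho <- config$cluster_correlation
  clusters <- unique(raters$cluster_id)
  raw <- with_seed(derive_seed(config$seed, 2L), {
    # one latent factor per (variant, cluster)
    Z <- base::matrix(stats::rnorm(n * length(clusters)), n,
                      dimnames = list(NULL, clusters))
    out <- base::matrix(NA_character_, n, nrow(raters),
                        dimnames = list(NULL, raters$name))
    for (j in seq_len(nrow(raters))) {
      eps <- stats::rnorm(n)
      u <- stats::pnorm(sqrt(rho) * Z[, raters$cluster_id[j]] +
                          sqrt(1 - rho) * eps)
      correct_prob <- ifelse(truth$truth_label == "non_neutral",
                             raters$sensitivity[j],
                             raters$specificity[j])
      correct <- u <= correct_prob
      call <- ifelse(truth$truth_label == "non_neutral",
                     ifelse(correct, "non_neutral", "neutral"),
                     ifelse(correct, "neutral", "non_neutral"))
      # truth-uncertain variants: positive calls at the configured rate,
      # through the same latent factor so cluster correlation carries over
      unc <- truth$truth_label == "uncertain"
      call[unc] <- ifelse(u[unc] <= config$positive_rate,
                          "non_neutral", "neutral")
      eq <- stats::runif(n) < raters$equivocal_rate[j]
      call[eq] <- "equivocal"
      out[, j] <- call
    }
    out
  })
  raw_call_table(truth, raw)
}

#' Attach scores consistent with simulated calls
#'
#' For each rater whose [predictor_spec()] carries a score rule, draws a
#' numeric score on the correct side of the cutoff for the rater's call,
#' landing inside the spec's low-confidence band with probability
#' `low_conf_rate` (and outside it otherwise). Raters without a score
#' rule are skipped with a warning. Equivocal calls get no score.
#'
#' @param table A `raw_call_table` with calls in the harmonized
#'   vocabulary (e.g. from [simulate_call_matrix()]).
#' @param specs Named list of [predictor_spec()] objects covering the
#'   raters to score.
#' @param low_conf_rate A single rate in \[0, 1\] or a named vector per
#'   rater.
#' @param seed RNG seed.
#' @return The `raw_call_table` with its `score` matrix filled in for
#'   the scored raters.
#' @export
simulate_scores <- function(table, specs, low_conf_rate = 0.1, seed = 1L) {
  stopifnot(inherits(table, "raw_call_table"))
  rates <- low_conf_rate
  if (is.null(names(rates))) {
    rates <- stats::setNames(rep(low_conf_rate[1L], length(specs)),
                             names(specs))
  }
  with_seed(derive_seed(seed, 3L), {
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      if (!nm %in% table$predictors) next
      if (is.null(spec$score_rule)) {
        warning("rater '", nm, "' has no score rule; skipped")
        next
      }
      rng <- spec$score_range %||% (spec$score_rule$cutoff + c(-5, 5))
      band <- spec$low_conf_band
      cutoff <- spec$score_rule$cutoff
      le <- spec$score_rule$direction == "le"
      call <- table$raw[, nm]
      score <- rep(NA_real_, length(call))
      for (side in c("non_neutral", "neutral")) {
        idx <- which(call == side)
        if (!length(idx)) next
        pos_side <- (side == "non_neutral") == le
        # closed interval of scores producing this call
        side_int <- if (pos_side) c(rng[1], cutoff) else c(cutoff, rng[2])
        in_band <- if (is.null(band)) c(NA, NA) else {
          c(max(side_int[1], band[1]), min(side_int[2], band[2]))
        }
        has_band <- !is.null(band) && in_band[1] < in_band[2]
        # pieces of the side interval outside the band
        out_pieces <- if (!has_band) list(side_int) else {
          ps <- list()
          if (side_int[1] < in_band[1]) ps <- c(ps, list(c(side_int[1], in_band[1])))
          if (in_band[2] < side_int[2]) ps <- c(ps, list(c(in_band[2], side_int[2])))
          ps
        }
        use_band <- has_band & (stats::runif(length(idx)) < rates[[nm]])
        if (!length(out_pieces)) use_band[] <- TRUE
        s <- numeric(length(idx))
        if (any(use_band)) {
          s[use_band] <- stats::runif(sum(use_band), in_band[1], in_band[2])
        }
        if (any(!use_band)) {
          lens <- vapply(out_pieces, diff, 0)
          pick <- sample.int(length(out_pieces), sum(!use_band),
                             replace = TRUE, prob = lens)
          s[!use_band] <- vapply(pick, function(k) {
            stats::runif(1L, out_pieces[[k]][1], out_pieces[[k]][2])
          }, 0)
        }
        score[idx] <- s
      }
      table$score[, nm] <- score
    }
    table
  })
}

#' Expand a cross-tabulation into per-variant calls and truth labels
#'
#' Inverts a [cross_tab()]: generates one variant per counted unit, with
#' the recorded truth label and raw prediction class, shuffled into a
#' seed-determined order. Re-tabulating the output reproduces the input
#' counts exactly, so performance statistics computed from the expansion
#' equal those implied by the printed cross-tabulation.
#'
#' @param crosstab A `cross_tab`.
#' @param seed RNG seed for the row shuffle.
#' @param spec Optional [predictor_spec()] used to harmonize the raw
#'   classes; defaults to the predictor's entry in
#'   [default_predictor_specs()] when available.
#' @return A data frame with columns `variant_id`, `truth_label`,
#'   `raw_class` and (when a spec is available) the harmonized `call`.
#' @export
calls_from_crosstab <- function(crosstab, seed = 1L, spec = NULL) {
  stopifnot(inherits(crosstab, "cross_tab"))
  if (is.null(spec)) {
    defaults <- default_predictor_specs()
    if (crosstab$predictor %in% names(defaults)) {
      spec <- defaults[[crosstab$predictor]]
    }
  }
  cl <- crosstab$classes
  truth_cols <- c(n_non_neutral = "non_neutral", n_neutral = "neutral",
                  n_uncertain = "uncertain")
  raw_class <- character()
  truth <- character()
  for (i in seq_len(nrow(cl))) {
    for (cc in names(truth_cols)) {
      k <- cl[[cc]][i]
      if (k > 0) {
        raw_class <- c(raw_class, rep(cl$class[i], k))
        truth <- c(truth, rep(truth_cols[[cc]], k))
      }
    }
  }
  n <- length(raw_class)
  ord <- with_seed(derive_seed(seed, 4L), sample.int(n))
  out <- data.frame(
    variant_id = sprintf("SNV%05d", seq_len(n)),
    truth_label = truth[ord],
    raw_class = raw_class[ord],
    stringsAsFactors = FALSE
  )
  if (!is.null(spec)) {
    out$call <- harmonize_column_binary(spec, out$raw_class,
                                        rep(NA_real_, n))
  }
  out
}
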
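two_cluster_raters <- function(n_per = 3, sens = 0.85, spec = 0.75,
                               equivocal = 0) {
  data.frame(
    name = paste0("r", seq_len(2 * n_per)),
    kind = "single",
    sensitivity = sens, specificity = spec, equivocal_rate = equivocal,
    cluster_id = rep(c("c1", "c2"), each = n_per),
    stringsAsFactors = FALSE
  )
}

test_that("truth labels match the configured cohort composition exactly", {
  cfg <- simulation_config(two_cluster_raters(), seed = 1L)
  tr <- simulate_truth_labels(cfg)
  counts <- table(tr$truth_label)
  expect_equal(as.integer(counts[c("non_neutral", "neutral", "uncertain")]),
               c(849L, 140L, 2602L))
  expect_false(anyDuplicated(tr$variant_id) > 0)
  expect_true(all(tr$gene_class %in% c("oncogene", "tsg", "new_cancer_gene")))

  cfg0 <- simulation_config(two_cluster_raters(), n_uncertain = 0L, seed = 1L)
  tr0 <- simulate_truth_labels(cfg0)
  expect_true(all(tr0$truth_label != "uncertain"))

  expect_identical(simulate_truth_labels(cfg), tr)
  expect_error(simulation_config(two_cluster_raters(), n_non_neutral = 0L,
                                 n_neutral = 0L, n_uncertain = 0L), "empty")
})

test_that("perfect raters reproduce the truth with unit agreement", {
  raters <- two_cluster_raters(n_per = 2, sens = 1, spec = 1)
  cfg <- simulation_config(raters, n_non_neutral = 200L, n_neutral = 100L,
                           n_uncertain = 0L, seed = 3L)
  tr <- simulate_truth_labels(cfg)
  tab <- simulate_call_matrix(tr, cfg)
  expect_true(all(tab$raw == tr$truth_label))
  m <- build_call_matrix(tab, synthetic_rater_specs(raters))
  km <- pairwise_kappa_matrix(m)
  expect_true(all(km$kappa == 1))
})

test_that("marginal rates converge to configured values at large n", {
  raters <- data.frame(name = "r1", kind = "single", sensitivity = 0.9,
                       specificity = 0.7, equivocal_rate = 0.1,
                       cluster_id = "c1", stringsAsFactors = FALSE)
  cfg <- simulation_config(raters, n_non_neutral = 5000L, n_neutral = 3000L,
                           n_uncertain = 0L, seed = 17L)
  tr <- simulate_truth_labels(cfg)
  tab <- simulate_call_matrix(tr, cfg)
  calls <- tab$raw[, "r1"]
  nn <- tr$truth_label == "non_neutral"

  eq_rate <- mean(calls == "equivocal")
  expect_lt(abs(eq_rate - 0.1), 3 * sqrt(0.1 * 0.9 / 8000))

  def_nn <- nn & calls != "equivocal"
  sens_hat <- mean(calls[def_nn] == "non_neutral")
  expect_lt(abs(sens_hat - 0.9), 3 * sqrt(0.9 * 0.1 / sum(def_nn)))

  def_ne <- !nn & calls != "equivocal"
  spec_hat <- mean(calls[def_ne] == "neutral")
  expect_lt(abs(spec_hat - 0.7), 3 * sqrt(0.7 * 0.3 / sum(def_ne)))

  expect_identical(simulate_call_matrix(tr, cfg)$raw, tab$raw)
})

test_that("cluster correlation produces the planted agreement structure", {
  raters <- two_cluster_raters(n_per = 3)
  cfg <- simulation_config(raters, n_non_neutral = 1500L, n_neutral = 500L,
                           n_uncertain = 0L, cluster_correlation = 0.8,
                           seed = 29L)
  tr <- simulate_truth_labels(cfg)
  m <- build_call_matrix(simulate_call_matrix(tr, cfg),
                         synthetic_rater_specs(raters))
  km <- pairwise_kappa_matrix(m,
                              groups = stats::setNames(raters$cluster_id,
                                                       raters$name))
  gs <- km$group_summary
  within <- gs$median_kappa[grepl("^within", gs$comparison)]
  between <- gs$median_kappa[!grepl("^within", gs$comparison)]
  expect_gt(min(within), max(between))
})

test_that("simulated scores respect call side and band occupancy", {
  specs <- default_predictor_specs()[c("PROVEAN", "SIFT", "VEST")]
  raters <- data.frame(name = names(specs), kind = "single",
                       sensitivity = 0.85, specificity = 0.65,
                       equivocal_rate = 0, cluster_id = "c1",
                       stringsAsFactors = FALSE)
  cfg <- simulation_config(raters, n_non_neutral = 2500L, n_neutral = 1500L,
                           n_uncertain = 0L, seed = 37L)
  tr <- simulate_truth_labels(cfg)
  tab <- simulate_call_matrix(tr, cfg)

  in_band <- function(spec, s) {
    !is.na(s) & s >= spec$low_conf_band[1] & s <= spec$low_conf_band[2]
  }
  t0 <- simulate_scores(tab, specs, low_conf_rate = 0, seed = 5L)
  for (nm in names(specs)) {
    expect_false(any(in_band(specs[[nm]], t0$score[, nm])))
    # scores reproduce the calls they were drawn for
    sc <- t0$score[, nm]
    redone <- vapply(which(!is.na(sc)), function(i)
      harmonize_call(specs[[nm]], score = sc[i]), "")
    expect_equal(unname(redone), unname(t0$raw[!is.na(sc), nm]))
  }

  t1 <- simulate_scores(tab, specs, low_conf_rate = 1, seed = 5L)
  m3 <- build_call_matrix(
    raw_call_table(tr, matrix(NA_character_, nrow(tr), 3,
                              dimnames = list(NULL, names(specs))),
                   t1$score),
    specs, mode = "three_category")
  expect_true(all(m3$calls == "low_confidence"))

  t3 <- simulate_scores(tab, specs, low_conf_rate = 0.3, seed = 5L)
  rate <- mean(in_band(specs$PROVEAN, t3$score[, "PROVEAN"]))
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))

  no_score_spec <- list(`Mutation Assessor` =
                          default_predictor_specs()[["Mutation Assessor"]])
  raters2 <- data.frame(name = "Mutation Assessor", kind = "single",
                        sensitivity = 0.8, specificity = 0.6,
                        equivocal_rate = 0, cluster_id = "c1",
                        stringsAsFactors = FALSE)
  cfg2 <- simulation_config(raters2, n_non_neutral = 50L, n_neutral = 20L,
                            n_uncertain = 0L, seed = 2L)
  tab2 <- simulate_call_matrix(simulate_truth_labels(cfg2), cfg2)
  expect_warning(simulate_scores(tab2, no_score_spec, 0.2, seed = 1L),
                 "no score rule")
})

test_that("cross-tab expansion is an exact, seed-shuffled inverse", {
  cts <- load_benchmark_crosstabs()
  for (ct in cts) {
    d <- calls_from_crosstab(ct, seed = 11L)
    retab <- table(factor(d$raw_class, levels = ct$classes$class),
                   factor(d$truth_label, levels = truth_levels()))
    expect_equal(unname(retab[, "neutral"]), ct$classes$n_neutral,
                 info = ct$predictor)
    expect_equal(unname(retab[, "non_neutral"]), ct$classes$n_non_neutral,
                 info = ct$predictor)
    expect_equal(unname(retab[, "uncertain"]), ct$classes$n_uncertain,
                 info = ct$predictor)
  }
  # harmonized call counts among labelled variants match the fixture
  d <- calls_from_crosstab(cts[["FATHMM (cancer)"]], seed = 11L)
  lab <- d$truth_label != "uncertain"
  expect_equal(sum(d$call[lab] == "non_neutral"), 71 + 831)
  expect_equal(sum(d$call[lab] == "neutral"), 69 + 18)

  # a one-cell cross-tab expands to a constant vector
  ct1 <- cross_tab("toy", data.frame(class = "Driver", n_neutral = 0,
                                     n_non_neutral = 7, n_uncertain = 0))
  d1 <- calls_from_crosstab(ct1, seed = 1L,
                            spec = predictor_spec("toy", "single",
                                                  c(driver = "non_neutral")))
  expect_equal(d1$raw_class, rep("Driver", 7))
  expect_equal(d1$call, rep("non_neutral", 7))

  expect_identical(calls_from_crosstab(cts[[1]], seed = 8L),
                   calls_from_crosstab(cts[[1]], seed = 8L))
})
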
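# Small labelled call matrix with known calls for rule tests.
make_vote_matrix <- function(calls, truth) {
  n <- nrow(calls)
  variants <- data.frame(
    variant_id = paste0("v", seq_len(n)), gene = "TP53", gene_class = "tsg",
    truth_label = truth, in_cosmic = FALSE, stringsAsFactors = FALSE
  )
  call_matrix(variants, calls)
}

test_that("rule enumeration matches the closed form and brute force", {
  expect_equal(nrow(enumerate_rules(letters[1:3])), 9L)   # 3*4 - 3

  r2 <- enumerate_rules(c("A", "B"))
  expect_equal(nrow(r2), 2L)
  expect_setequal(r2$p, c(1L, 2L))
  expect_true(all(r2$members_str == "A + B"))

  for (N in 3:6) {
    rules <- enumerate_rules(letters[1:N])
    expect_equal(nrow(rules), N * 2^(N - 1) - N)
    # independent brute force: loop subsets x thresholds
    brute <- character()
    for (n in 2:N) {
      for (s in utils::combn(letters[1:N], n, simplify = FALSE)) {
        for (p in 1:n) {
          brute <- c(brute, paste(paste(s, collapse = " + "), p))
        }
      }
    }
    expect_setequal(paste(rules$members_str, rules$p), brute)
    expect_false(anyDuplicated(rules$rule_id) > 0)
  }

  expect_error(enumerate_rules(c("A", "A")), "duplicate")
})

test_that("voting rules use OR/AND semantics with abstaining equivocals", {
  calls <- cbind(A = c("non_neutral", "neutral", "non_neutral"),
                 B = c("neutral", "neutral", "equivocal"))
  m <- make_vote_matrix(calls, rep("non_neutral", 3))
  expect_equal(apply_rule(list(members = c("A", "B"), p = 1), m),
               c("non_neutral", "neutral", "non_neutral"))
  expect_equal(apply_rule(list(members = c("A", "B"), p = 2), m),
               c("neutral", "neutral", "neutral"))
  expect_error(apply_rule(list(members = c("A", "Z"), p = 1), m), "Z")
})

test_that("splits have the expected sizes and are seed-deterministic", {
  ids <- paste0("v", 1:989)
  cfg <- split_config(fraction_subset1 = 2 / 3, seed = 4L)
  sp <- split_dataset(ids, cfg, iteration = 1)
  expect_length(sp$subset1, 659L)
  expect_length(sp$subset2, 330L)
  expect_setequal(c(sp$subset1, sp$subset2), ids)
  expect_length(intersect(sp$subset1, sp$subset2), 0L)
  expect_identical(split_dataset(ids, cfg, iteration = 1), sp)
  expect_false(identical(split_dataset(ids, cfg, iteration = 2), sp))

  sp4 <- split_dataset(paste0("v", 1:4),
                       split_config(fraction_subset1 = 0.5, seed = 1L), 1)
  expect_length(sp4$subset1, 2L)
  expect_length(sp4$subset2, 2L)

  # stratified splits keep the label balance
  variants <- data.frame(variant_id = ids,
                         truth_label = rep(c("non_neutral", "neutral"),
                                           c(849, 140)),
                         stringsAsFactors = FALSE)
  cfg_s <- split_config(fraction_subset1 = 2 / 3, seed = 4L, stratified = TRUE)
  sps <- split_dataset(variants, cfg_s, 1)
  n_ne1 <- sum(variants$truth_label[variants$variant_id %in% sps$subset1] ==
                 "neutral")
  expect_equal(n_ne1, 93L)  # round(140 * 2/3)
})

test_that("a single repetition reproduces directly computed split metrics", {
  set.seed(12)
  truth <- rep(c("non_neutral", "neutral"), c(60, 40))
  calls <- cbind(
    A = ifelse(runif(100) < 0.8, ifelse(truth == "non_neutral",
                                        "non_neutral", "neutral"),
               ifelse(truth == "non_neutral", "neutral", "non_neutral")),
    B = sample(c("non_neutral", "neutral"), 100, TRUE)
  )
  m <- make_vote_matrix(calls, truth)
  rules <- enumerate_rules(c("A", "B"))
  cfg <- split_config(repetitions = 1L, seed = 99L)
  ev <- evaluate_over_splits(rules, m, config = cfg)

  sp <- split_dataset(m$variants, cfg, 1)
  for (s in 1:2) {
    idx <- m$variants$variant_id %in% sp[[s]]
    for (r in 1:2) {
      direct <- performance_stats(confusion_counts(
        apply_rule(rules[r, ], m)[idx], truth[idx]))
      row <- ev[ev$subset == s & ev$rule_id == rules$rule_id[r], ]
      expect_equal(row$accuracy_mean, direct$accuracy)
      expect_equal(row$npv_mean, direct$npv)
      expect_equal(row$composite_mean, direct$composite)
    }
  }
})

test_that("raising the vote threshold trades sensitivity for specificity", {
  set.seed(23)
  truth <- rep(c("non_neutral", "neutral"), c(300, 200))
  calls <- sapply(1:5, function(j) {
    ok <- runif(500) < 0.8
    ifelse(truth == "non_neutral",
           ifelse(ok, "non_neutral", "neutral"),
           ifelse(ok, "neutral", "non_neutral"))
  })
  colnames(calls) <- paste0("r", 1:5)
  m <- make_vote_matrix(calls, truth)
  members <- paste0("r", 1:5)
  stats_p <- lapply(1:5, function(p) {
    performance_stats(confusion_counts(
      apply_rule(list(members = members, p = p), m), truth))
  })
  sens <- vapply(stats_p, `[[`, 0, "sensitivity")
  spec <- vapply(stats_p, `[[`, 0, "specificity")
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))

  # OR dominates member sensitivities; AND dominates member specificities
  member_stats <- panel_performance(m)
  expect_gte(sens[1], max(vapply(member_stats, `[[`, 0, "sensitivity")))
  expect_gte(spec[5], max(vapply(member_stats, `[[`, 0, "specificity")))
})

test_that("evaluation is byte-identical under a fixed seed", {
  set.seed(5)
  truth <- rep(c("non_neutral", "neutral"), c(80, 40))
  calls <- cbind(A = sample(c("non_neutral", "neutral"), 120, TRUE),
                 B = sample(c("non_neutral", "neutral"), 120, TRUE),
                 C = sample(c("non_neutral", "neutral"), 120, TRUE))
  m <- make_vote_matrix(calls, truth)
  rules <- enumerate_rules(c("A", "B", "C"))
  cfg <- split_config(repetitions = 20L, seed = 7L)
  ev1 <- evaluate_over_splits(rules, m, config = cfg)
  ev2 <- evaluate_over_splits(rules, m, config = cfg)
  expect_identical(ev1, ev2)
})

test_that("ranking flags improvements but never a rule equal to baseline", {
  set.seed(6)
  truth <- rep(c("non_neutral", "neutral"), c(200, 100))
  good <- ifelse(truth == "non_neutral",
                 ifelse(runif(300) < 0.9, "non_neutral", "neutral"),
                 ifelse(runif(300) < 0.8, "neutral", "non_neutral"))
  noise <- sample(c("non_neutral", "neutral"), 300, TRUE)
  m <- make_vote_matrix(cbind(A = good, B = noise), truth)
  cfg <- split_config(repetitions = 50L, seed = 13L)
  singles <- evaluate_over_splits(singleton_rules(c("A", "B")), m, config = cfg)
  baseline <- singles[singles$members_str == "A", ]
  ranked <- rank_rules(singles, by = "accuracy",
                       baselines = list(single = baseline))
  self <- ranked[ranked$members_str == "A", ]
  expect_false(self$beats_single_both)
  expect_false(self$sig_single_both)
  # ranks are a permutation
  expect_setequal(ranked$rank_by_accuracy_s1, seq_len(nrow(ranked)))
})

test_that("top-k recurrence counts members and respects the bound k", {
  set.seed(9)
  truth <- rep(c("non_neutral", "neutral"), c(100, 60))
  calls <- sapply(1:4, function(j) sample(c("non_neutral", "neutral"),
                                          160, TRUE))
  colnames(calls) <- LETTERS[1:4]
  m <- make_vote_matrix(calls, truth)
  ev <- evaluate_over_splits(enumerate_rules(LETTERS[1:4]), m,
                             config = split_config(repetitions = 10L, seed = 2L))
  ranked <- rank_rules(ev, by = "accuracy")
  rec1 <- recurrence_in_top(ranked, 1)
  top1 <- ranked$members[[which(ranked$rank_by_accuracy_s1 == 1)]]
  r1 <- rec1[rec1$criterion == "accuracy" & rec1$subset == 1, ]
  expect_equal(sort(r1$predictor[r1$count == 1]), sort(top1))
  expect_equal(sum(r1$count), length(top1))

  rec10 <- recurrence_in_top(ranked, 10)
  expect_true(all(rec10$count <= 10))
  expect_error(recurrence_in_top(ranked, nrow(ranked) + 1), "exceeds")
})

test_that("the (n, p) grid covers only feasible cells", {
  set.seed(10)
  truth <- rep(c("non_neutral", "neutral"), c(100, 60))
  calls <- sapply(1:4, function(j) sample(c("non_neutral", "neutral"),
                                          160, TRUE))
  colnames(calls) <- LETTERS[1:4]
  m <- make_vote_matrix(calls, truth)

  one <- enumerate_rules(LETTERS[1:2])
  one <- one[one$p == 1 & one$n == 2, ]
  ev1 <- evaluate_over_splits(one, m,
                              config = split_config(repetitions = 5L, seed = 3L))
  g1 <- np_grid_summary(ev1)
  expect_equal(nrow(g1), 2L)  # one (n, p) cell per subset
  expect_equal(g1$mean_accuracy, g1$max_accuracy)

  ev <- evaluate_over_splits(enumerate_rules(LETTERS[1:4]), m,
                             config = split_config(repetitions = 5L, seed = 3L))
  g <- np_grid_summary(ev)
  expect_true(all(g$p <= g$n))
  expect_equal(nrow(g), 2L * (3 + 4 + 2))  # n=2..4 with p=1..n, both subsets
})
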
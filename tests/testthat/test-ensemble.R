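test_that("a single-member probability sum reduces to plain prediction", {
  tax <- toy_taxonomy()
  m <- random_prob_matrix(20, tax, seed = 3)
  inp <- ensemble_input(list(m))
  for (lvl in c("class", "subclass", "sub-subclass")) {
    dec <- probability_sum_ensemble(inp, tax, lvl)
    expect_identical(dec$label, predict_label(m, tax, lvl))
  }
})

test_that("probability-sum scores equal the brute-force model sum", {
  tax <- toy_taxonomy()
  mats <- lapply(1:5, function(i) random_prob_matrix(12, tax, seed = 7 + i))
  inp <- ensemble_input(mats)
  dec <- probability_sum_ensemble(inp, tax, "subclass")
  scores <- attr(dec, "scores")
  # oracle: per document, per subclass, loop over models and leaves
  for (d in 1:12) {
    for (s in level_labels(tax, "subclass")) {
      acc <- 0
      for (m in mats) {
        for (lf in tax$leaf_order) {
          if (ancestor(tax, lf, "subclass") == s) acc <- acc + m[d, lf]
        }
      }
      expect_equal(scores[d, s], acc, tolerance = 1e-12)
    }
    best <- names(which.max(scores[d, ]))
    expect_identical(dec$label[d], best)
  }
  expect_true(all(dec$score <= 5 + 1e-12))
  norm <- probability_sum_ensemble(inp, tax, "subclass", normalize = TRUE)
  expect_equal(norm$score, dec$score / 5)
})

test_that("probability sum is invariant to model order and breaks ties first-in-order", {
  tax <- toy_taxonomy()
  mats <- lapply(1:4, function(i) random_prob_matrix(10, tax, seed = 40 + i))
  a <- probability_sum_ensemble(ensemble_input(mats), tax, "subclass")
  b <- probability_sum_ensemble(ensemble_input(rev(mats)), tax, "subclass")
  expect_identical(a$label, b$label)
  expect_equal(a$score, b$score)
  # two exactly opposite one-hots: all classes tie -> first label in order
  m1 <- onehot_matrix("a1", tax)
  m2 <- onehot_matrix("c1", tax)
  tie <- probability_sum_ensemble(ensemble_input(list(m1, m2)), tax, "class")
  expect_identical(tie$label, "orig")
})

test_that("vote casting honors the per-vote probability threshold", {
  tax <- default_taxonomy()
  set.seed(5)
  g <- matrix(stats::rgamma(10 * 22, 1), 10, 22)
  m <- prob_matrix(g / rowSums(g), sprintf("d%02d", 1:10), tax)
  inp <- ensemble_input(list(m, m))
  # binary class level: the larger of two probabilities is always >= 0.5
  v_class <- cast_votes(inp, tax, "class", t_v = 0.5)
  expect_false(anyNA(v_class))
  # near-uniform 22-leaf rows can never reach 0.5
  u <- prob_matrix(matrix(1 / 22, 3, 22), c("u1", "u2", "u3"), tax)
  v_leaf <- cast_votes(ensemble_input(list(u)), tax, "sub-subclass", t_v = 0.5)
  expect_true(all(is.na(v_leaf)))
  # t_v = 0 lets every model vote its argmax
  v0 <- cast_votes(inp, tax, "sub-subclass", t_v = 0)
  expect_false(anyNA(v0))
  expect_identical(unname(v0[, 1]), predict_label(m, tax, "sub-subclass"))
})

test_that("worked voting examples: thresholds, dynamic rules, ties", {
  tax <- toy_taxonomy()
  # 5 models voting at subclass level: {sa: 3, sb: 1, sc: 1}
  mats <- lapply(c("a1", "a2", "a1", "b1", "c1"), onehot_matrix, tax = tax)
  inp <- ensemble_input(mats)
  dec <- voting_ensemble(inp, tax, "subclass", voting_config(t = 3))
  expect_identical(dec$label, "sa")

  # 2 abstentions, remaining votes {sa: 2, sb: 1}
  uniform <- prob_matrix(matrix(0.2, 1, 5), "d001", tax)
  mats2 <- list(onehot_matrix("a1", tax), onehot_matrix("a2", tax),
                onehot_matrix("b1", tax), uniform, uniform)
  inp2 <- ensemble_input(mats2)
  maj <- voting_ensemble(inp2, tax, "subclass",
                         voting_config(t_v = 0.5, rule = "majority",
                                       dynamic = TRUE))
  expect_identical(maj$label, "sa")
  expect_identical(maj$threshold, 2L)
  una <- voting_ensemble(inp2, tax, "subclass",
                         voting_config(t_v = 0.5, rule = "unanimity",
                                       dynamic = TRUE))
  expect_identical(una$label, "UNKNOWN")
  expect_identical(una$threshold, 3L)

  # tie {sa: 2, sc: 2, sb: 1} at t = 2 -> UNKNOWN
  mats3 <- lapply(c("a1", "a1", "c1", "c2", "b1"), onehot_matrix, tax = tax)
  tie <- voting_ensemble(ensemble_input(mats3), tax, "subclass",
                         voting_config(t = 2))
  expect_identical(tie$label, "UNKNOWN")

  # binary level, 5 models, t = 3, t_v = 0.5: a decision always exists
  set.seed(8)
  mats4 <- lapply(1:5, function(i) random_prob_matrix(30, tax, seed = 50 + i))
  dec4 <- voting_ensemble(ensemble_input(mats4), tax, "class",
                          voting_config(t = 3, t_v = 0.5))
  expect_false(any(dec4$label == "UNKNOWN"))

  expect_error(voting_ensemble(inp, tax, "class", voting_config(t = 6)),
               "exceeds")
})

test_that("voting matches the exhaustive brute-force tally on all 3^5 patterns", {
  tax <- toy_taxonomy()
  labs <- level_labels(tax, "subclass")
  leaf_of <- c(sa = "a1", sb = "b1", sc = "c1")
  patterns <- expand.grid(rep(list(labs), 5), stringsAsFactors = FALSE)
  expect_equal(nrow(patterns), 243)
  for (t in c(1, 3, 5)) {
    for (i in seq_len(nrow(patterns))) {
      cast <- unlist(patterns[i, ], use.names = FALSE)
      inp <- ensemble_input(lapply(leaf_of[cast], onehot_matrix, tax = tax))
      got <- voting_ensemble(inp, tax, "subclass", voting_config(t = t))
      expect_identical(got$label,
                       oracle_vote_decision(cast, labs, "threshold", t, 5))
    }
  }
})

test_that("dynamic rules match the oracle on vote patterns with abstention", {
  tax <- toy_taxonomy()
  labs <- level_labels(tax, "subclass")
  piece <- list(sa = onehot_matrix("a1", tax), sb = onehot_matrix("b1", tax),
                ABSTAIN = prob_matrix(matrix(0.2, 1, 5), "d001", tax))
  patterns <- expand.grid(rep(list(names(piece)), 5),
                          stringsAsFactors = FALSE)
  for (rule in c("majority", "unanimity")) {
    for (i in seq_len(nrow(patterns))) {
      picks <- unlist(patterns[i, ], use.names = FALSE)
      inp <- ensemble_input(lapply(piece[picks], identity))
      got <- voting_ensemble(inp, tax, "subclass",
                             voting_config(t_v = 0.5, rule = rule,
                                           dynamic = TRUE))
      cast <- ifelse(picks == "ABSTAIN", NA_character_, picks)
      cast <- ifelse(is.na(cast), NA_character_,
                     c(sa = "sa", sb = "sb")[cast])
      expect_identical(got$label,
                       oracle_vote_decision(cast, labs, rule, NA, 5))
    }
  }
})

test_that("coverage shrinks as vote thresholds tighten", {
  tax <- toy_taxonomy()
  truth <- sample(tax$leaf_order, 80, replace = TRUE)
  inp <- simulate_predictions(truth, tax,
                              prediction_config(concentration = 3, seed = 77))
  for (tv in c(0, 0.4, 0.8)) {
    covs <- vapply(1:5, function(t) {
      coverage(voting_ensemble(inp, tax, "subclass",
                               voting_config(t = t, t_v = tv)))
    }, numeric(1))
    expect_true(all(diff(covs) <= 0))
  }
  # at t >= 3 of 5 a winning tally is automatically the unique maximum, so
  # raising t_v can only remove decisions (at lower t a raised t_v may
  # break a tie and create one)
  for (t in c(3, 5)) {
    covs <- vapply(c(0, 0.3, 0.6, 0.9), function(tv) {
      coverage(voting_ensemble(inp, tax, "subclass",
                               voting_config(t = t, t_v = tv)))
    }, numeric(1))
    expect_true(all(diff(covs) <= 0))
  }
})

test_that("documents decided under static unanimity are decided under majority", {
  tax <- toy_taxonomy()
  set.seed(91)
  truth <- sample(tax$leaf_order, 60, replace = TRUE)
  inp <- simulate_predictions(truth, tax,
                              prediction_config(concentration = 5, seed = 91))
  una <- voting_ensemble(inp, tax, "subclass", voting_config(t = 5))
  maj <- voting_ensemble(inp, tax, "subclass", voting_config(t = 3))
  decided <- una$label != "UNKNOWN"
  expect_true(all(maj$label[decided] == una$label[decided]))
})

test_that("coverage handles the edge cases", {
  d_all <- tibble::tibble(label = c("a", "b", "c"))
  expect_equal(coverage(d_all), 1)
  d_none <- tibble::tibble(label = rep("UNKNOWN", 4))
  expect_equal(coverage(d_none), 0)
  d_mix <- tibble::tibble(label = c(rep("a", 80), rep("UNKNOWN", 20)))
  expect_equal(coverage(d_mix), 0.8)
  expect_error(coverage(d_all[0, , drop = FALSE]), "undefined")
})
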
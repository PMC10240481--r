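test_that("contingency counts behave one-vs-rest", {
  cts <- contingency(c("A", "A", "B"), c("A", "B", "B"), "A")
  expect_equal(cts, list(tp = 1L, fp = 0L, fn = 1L, tn = 1L),
               ignore_attr = TRUE)
  perfect <- contingency(c("A", "B", "A"), c("A", "B", "A"), "A")
  expect_equal(perfect$fp + perfect$fn, 0)
  all_pos <- contingency(c("A", "B", "B"), c("A", "A", "A"), "A")
  expect_equal(all_pos$tn, 0)
  expect_error(contingency(c("A"), c("A", "B"), "A"), "equal length")
})

test_that("precision, recall, F1 and fp rate follow their definitions", {
  cts <- list(tp = 3, fp = 1, fn = 2, tn = 4)
  expect_equal(precision_score(cts), 0.75)
  expect_equal(recall_score(cts), 0.6)
  expect_equal(f1_score(cts), 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(fp_rate(cts), 1 / 5)
  # harmonic-mean fixed point: precision = recall = p gives F1 = p
  p_eq <- list(tp = 4, fp = 1, fn = 1, tn = 3)
  expect_equal(f1_score(p_eq), precision_score(p_eq))
  # zero-denominator convention
  none <- list(tp = 0, fp = 0, fn = 3, tn = 5)
  expect_equal(precision_score(none), 0)
  expect_equal(f1_score(none), 0)
})

test_that("micro average equals accuracy for single-label multiclass", {
  set.seed(13)
  labs <- c("x", "y", "z")
  y_true <- sample(labs, 60, replace = TRUE)
  y_pred <- ifelse(stats::runif(60) < 0.6, y_true,
                   sample(labs, 60, replace = TRUE))
  rep <- metrics_by_label(y_true, y_pred, labs)
  acc <- mean(y_true == y_pred)
  expect_equal(unname(rep$micro["precision"]), acc)
  expect_equal(unname(rep$micro["recall"]), acc)
  expect_equal(unname(rep$micro["f1"]), acc)
})

test_that("macro average is the unweighted per-label mean", {
  # two labels with F1 0.8 and 0.4 -> macro F1 0.6
  c1 <- list(tp = 4, fp = 1, fn = 1, tn = 4) # F1 = 0.8
  c2 <- list(tp = 1, fp = 1, fn = 2, tn = 6) # F1 = 0.4
  agg <- micro_macro(list(c1, c2))
  expect_equal(unname(agg$macro["f1"]), 0.6)
  # a dominant label drags micro but not macro
  big_good <- list(tp = 90, fp = 2, fn = 2, tn = 6)
  small_bad <- list(tp = 1, fp = 8, fn = 7, tn = 84)
  agg2 <- micro_macro(list(big_good, small_bad))
  expect_gt(unname(agg2$micro["f1"]), unname(agg2$macro["f1"]))
})

test_that("confusion matrices count truth rows against prediction columns", {
  tax <- toy_taxonomy()
  y_true <- c("a1", "a1", "a2", "b1", "c1")
  cm <- confusion_matrix(y_true, y_true, tax, "sub-subclass")
  expect_equal(sum(cm), 5)
  expect_equal(sum(diag(cm)), 5)
  y_pred <- rep("b1", 5)
  cm2 <- confusion_matrix(y_true, y_pred, tax, "sub-subclass")
  expect_equal(unname(colSums(cm2)["b1"]), 5)
  expect_equal(sum(cm2[, setdiff(colnames(cm2), "b1")]), 0)
  # leaf labels roll up automatically at coarser levels
  cm3 <- confusion_matrix(y_true, y_pred, tax, "class")
  expect_equal(unname(cm3["orig", "orig"]), 4)
  expect_equal(unname(cm3["nonorig", "orig"]), 1)
  expect_equal(rowSums(cm3),
               c(orig = 4, nonorig = 1))
})

test_that("AUC-ROC matches the Mann-Whitney formulation and its symmetries", {
  tax <- toy_taxonomy()
  set.seed(11)
  for (rep_i in 1:10) {
    pos <- stats::runif(40) < 0.4
    score <- ifelse(pos, stats::rnorm(40, 1), stats::rnorm(40))
    expect_equal(littriage:::auc_binary(pos, score),
                 oracle_auc_u(pos, score), tolerance = 1e-12)
    expect_equal(littriage:::auc_binary(pos, -score),
                 1 - oracle_auc_u(pos, score), tolerance = 1e-12)
  }
  # tied scores: midrank oracle still agrees with the trapezoid sweep
  pos <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  score <- c(0.9, 0.5, 0.5, 0.1, 0.5, 0.9)
  expect_equal(littriage:::auc_binary(pos, score), oracle_auc_u(pos, score),
               tolerance = 1e-12)
})

test_that("macro one-vs-rest AUC is 1 for perfect scores and ~0.5 for noise", {
  tax <- toy_taxonomy()
  truth <- sample(tax$leaf_order, 50, replace = TRUE)
  perfect <- onehot_matrix(truth, tax)
  expect_equal(as.numeric(roc_auc(truth, perfect, tax, "subclass")), 1)
  noise <- random_prob_matrix(2000, tax, seed = 11)
  set.seed(11)
  truth_big <- sample(tax$leaf_order, 2000, replace = TRUE)
  auc <- as.numeric(roc_auc(truth_big, noise, tax, "subclass"))
  expect_lt(abs(auc - 0.5), 0.03)
  # absent labels are skipped with one warning each
  w <- testthat::capture_warnings(
    roc_auc(rep("a1", 10), random_prob_matrix(10, tax, 3), tax, "subclass"))
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 3) # sb and sc absent, sa one-class
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  tax <- toy_taxonomy()
  set.seed(19)
  truth <- sample(tax$leaf_order, 80, replace = TRUE)
  probs <- random_prob_matrix(80, tax, seed = 19)
  got <- roc_auc(truth, probs, tax, "class")
  per_label <- attr(got, "per_label")
  rolled_orig <- rowSums(probs[, c("a1", "a2", "b1")])
  ref <- pROC::auc(pROC::roc(truth %in% c("a1", "a2", "b1"), rolled_orig,
                             quiet = TRUE, direction = "<"))
  expect_equal(unname(per_label["orig"]), as.numeric(ref), tolerance = 1e-12)
})

test_that("bootstrap CIs are seed-reproducible and bracket the point", {
  set.seed(23)
  y <- stats::rnorm(100)
  metric <- function(idx) mean(y[idx])
  a <- bootstrap_ci(metric, 100, n_boot = 500, seed = 42)
  b <- bootstrap_ci(metric, 100, n_boot = 500, seed = 42)
  expect_identical(a, b)
  expect_lte(a$lower, a$point)
  expect_gte(a$upper, a$point)
  # a constant metric collapses the interval
  const <- bootstrap_ci(function(idx) 0.7, 10, n_boot = 100, seed = 1)
  expect_equal(const$lower, 0.7)
  expect_equal(const$upper, 0.7)
  # undefined resamples are redrawn and counted
  flaky <- function(idx) if (1 %in% idx) NA_real_ else mean(y[idx])
  r <- bootstrap_ci(flaky, 5, n_boot = 50, seed = 3)
  expect_gt(r$n_redrawn, 0)
})

test_that("more bootstrap replicates stabilize the percentile estimates", {
  set.seed(29)
  y <- stats::rnorm(80)
  metric <- function(idx) mean(y[idx])
  spread <- function(n_boot) {
    uppers <- vapply(1:20, function(s) {
      bootstrap_ci(metric, 80, n_boot = n_boot, seed = s)$upper
    }, numeric(1))
    stats::sd(uppers)
  }
  expect_lt(spread(800), spread(100))
})

test_that("McNemar switches between exact and corrected chi-square forms", {
  # symmetric discordance: p = 1
  ca <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 10))
  cb <- c(rep(FALSE, 5), rep(TRUE, 5), rep(TRUE, 10))
  sym <- mcnemar_test(ca, cb)
  expect_gte(sym$p_value, 0.99)
  # b = 10, c = 0: exact two-sided binomial 2 * (1/2)^10
  ca2 <- c(rep(TRUE, 10), rep(TRUE, 5))
  cb2 <- c(rep(FALSE, 10), rep(TRUE, 5))
  ex <- mcnemar_test(ca2, cb2)
  expect_equal(ex$p_value, 2 * (0.5)^10, tolerance = 1e-12)
  expect_identical(ex$method, "exact binomial")
  # b = 40, c = 20: corrected statistic (|40-20|-1)^2 / 60
  ca3 <- c(rep(TRUE, 40), rep(FALSE, 20), rep(TRUE, 10))
  cb3 <- c(rep(FALSE, 40), rep(TRUE, 20), rep(TRUE, 10))
  chi <- mcnemar_test(ca3, cb3)
  expect_equal(chi$statistic, 361 / 60, tolerance = 1e-12)
  ref <- stats::mcnemar.test(table(ca3, cb3), correct = TRUE)
  expect_equal(chi$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(chi$p_value, ref$p.value, tolerance = 1e-12)
  # no discordance
  none <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(none$p_value, 1)
  expect_equal(none$statistic, 0)
})

test_that("PR curves sweep thresholds down to full recall", {
  set.seed(31)
  y <- sample(c("pos", "neg"), 60, replace = TRUE, prob = c(0.3, 0.7))
  perfect <- ifelse(y == "pos", 0.9, 0.1)
  pc <- pr_curve(y, perfect, "pos")
  # a perfect separator reaches precision 1 at recall 1 before the sweep
  # passes into the negatives
  expect_true(any(pc$recall == 1 & pc$precision == 1))
  expect_true(all(pc$precision[pc$recall < 1] == 1))
  expect_equal(max(pc$recall), 1)
  # random scores: precision near prevalence at the high-recall end
  noise <- stats::runif(2000)
  y2 <- sample(c("pos", "neg"), 2000, replace = TRUE, prob = c(0.3, 0.7))
  pc2 <- pr_curve(y2, noise, "pos")
  tail_prec <- pc2$precision[pc2$recall > 0.95]
  expect_lt(abs(mean(tail_prec) - 0.3), 0.05)
  expect_error(pr_curve(rep("pos", 5), stats::runif(5), "pos"), "both")
})
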
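#' One-vs-rest contingency counts for a label
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param label the target label.
#' @return list with `tp`, `fp`, `fn`, `tn`; counts total `length(y_true)`.
#' @export
contingency <- function(y_true, y_pred, label) {
  if (length(y_true) != length(y_pred)) {
    stop_littriage("y_true and y_pred must have equal length",
                   "littriage_validation_error")
  }
  pt <- y_true == label
  pp <- y_pred == label
  list(tp = sum(pt & pp), fp = sum(!pt & pp),
       fn = sum(pt & !pp), tn = sum(!pt & !pp))
}

#' Precision, recall, F1 and false-positive rate from counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`, F1 their harmonic
#' mean, `fp_rate = fp/(fp+tn)`. A zero denominator yields 0 (and F1 is 0
#' whenever `tp = 0`), which keeps macro averages defined for labels a
#' model never predicts.
#'
#' @param counts a list from [contingency()].
#' @return a single numeric value.
#' @export
precision_score <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0) 0 else counts$tp / d
}

#' @rdname precision_score
#' @export
recall_score <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) 0 else counts$tp / d
}

#' @rdname precision_score
#' @export
f1_score <- function(counts) {
  p <- precision_score(counts); r <- recall_score(counts)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' @rdname precision_score
#' @export
fp_rate <- function(counts) {
  d <- counts$fp + counts$tn
  if (d == 0) 0 else counts$fp / d
}

#' Per-label and aggregate classification metrics
#'
#' Computes one-vs-rest counts and precision/recall/F1 for every label of
#' the level, plus micro averages (metrics of the pooled counts; for
#' single-label data these all equal accuracy) and macro averages
#' (unweighted means over labels, sensitive to rare labels).
#'
#' @param y_true,y_pred label vectors at the same taxonomy level.
#' @param labels the level's full label set (defaults to the labels seen).
#' @return list with `per_label` (tibble: label, tp, fp, fn, tn,
#'   precision, recall, f1), `micro` and `macro` (named numeric vectors
#'   with precision, recall, f1), and `n` evaluated documents.
#' @export
metrics_by_label <- function(y_true, y_pred, labels = NULL) {
  labels <- labels %||% sort(unique(c(y_true, y_pred)))
  counts <- lapply(labels, function(l) contingency(y_true, y_pred, l))
  per_label <- tibble::tibble(
    label = labels,
    tp = vapply(counts, `[[`, numeric(1), "tp"),
    fp = vapply(counts, `[[`, numeric(1), "fp"),
    fn = vapply(counts, `[[`, numeric(1), "fn"),
    tn = vapply(counts, `[[`, numeric(1), "tn"),
    precision = vapply(counts, precision_score, numeric(1)),
    recall = vapply(counts, recall_score, numeric(1)),
    f1 = vapply(counts, f1_score, numeric(1))
  )
  agg <- micro_macro(counts)
  list(per_label = per_label, micro = agg$micro, macro = agg$macro,
       n = length(y_true))
}

#' Micro and macro metric aggregates
#'
#' @param counts_list list of [contingency()] count lists, one per label.
#' @return list with `micro` and `macro`, each a named numeric vector of
#'   precision, recall and f1.
#' @export
micro_macro <- function(counts_list) {
  pooled <- list(tp = sum(vapply(counts_list, `[[`, numeric(1), "tp")),
                 fp = sum(vapply(counts_list, `[[`, numeric(1), "fp")),
                 fn = sum(vapply(counts_list, `[[`, numeric(1), "fn")),
                 tn = sum(vapply(counts_list, `[[`, numeric(1), "tn")))
  micro <- c(precision = precision_score(pooled),
             recall = recall_score(pooled),
             f1 = f1_score(pooled))
  macro <- c(precision = mean(vapply(counts_list, precision_score, numeric(1))),
             recall = mean(vapply(counts_list, recall_score, numeric(1))),
             f1 = mean(vapply(counts_list, f1_score, numeric(1))))
  list(micro = micro, macro = macro)
}

#' Confusion matrix at a taxonomy level
#'
#' @param y_true,y_pred label vectors (leaf ids or level-label ids; leaf
#'   ids are rolled up via [ancestor()]).
#' @param tax the [taxonomy()].
#' @param level taxonomy level.
#' @return square integer matrix in level-label order; entry `(i, j)`
#'   counts truth `i` predicted `j`.
#' @export
confusion_matrix <- function(y_true, y_pred, tax, level) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  labs <- level_labels(tax, level)
  lift <- function(y) {
    ifelse(y %in% tax$leaf_order & !(y %in% labs),
           ancestor_vec(tax, y, level), y)
  }
  y_true <- lift(y_true); y_pred <- lift(y_pred)
  tab <- table(factor(y_true, levels = labs), factor(y_pred, levels = labs))
  m <- matrix(as.integer(tab), nrow = length(labs),
              dimnames = list(truth = labs, predicted = labs))
  m
}

# vectorized ancestor that tolerates non-leaf entries untouched
ancestor_vec <- function(tax, ids, level) {
  out <- ids
  is_leaf <- ids %in% tax$leaf_order
  if (any(is_leaf)) out[is_leaf] <- ancestor(tax, ids[is_leaf], level)
  out
}

#' Macro one-vs-rest AUC-ROC
#'
#' For each level label, sweeps a threshold over that label's rolled-up
#' probability, traces the ROC (true-positive rate vs false-positive
#' rate) and integrates it by the trapezoidal rule; the level's AUC is
#' the unweighted mean over labels present in the truth. Labels absent
#' from the truth are skipped with a warning.
#'
#' @param y_true label vector at `level` (or leaf ids, rolled up).
#' @param probs a [prob_matrix()] of leaf probabilities.
#' @param tax the [taxonomy()].
#' @param level taxonomy level.
#' @return macro-averaged AUC in `[0, 1]`; per-label AUCs as attribute
#'   `per_label`.
#' @export
roc_auc <- function(y_true, probs, tax, level) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  labs <- level_labels(tax, level)
  y_true <- ancestor_vec(tax, y_true, level)
  rolled <- rollup_matrix(tax, probs, level)
  aucs <- stats::setNames(rep(NA_real_, length(labs)), labs)
  for (l in labs) {
    pos <- y_true == l
    if (!any(pos) || all(pos)) {
      warning(sprintf("label '%s' absent from truth (or truth one-class); skipped",
                      l), call. = FALSE)
      next
    }
    aucs[l] <- auc_binary(pos, rolled[, l])
  }
  out <- mean(aucs, na.rm = TRUE)
  attr(out, "per_label") <- aucs
  out
}

# trapezoidal AUC via explicit threshold sweep over the distinct scores
auc_binary <- function(pos, score) {
  thr <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tpr <- c(0, vapply(thr, function(t) sum(score >= t & pos), numeric(1)) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(score >= t & !pos), numeric(1)) / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Percentile bootstrap confidence interval of a metric
#'
#' Resamples documents with replacement `n_boot` times, evaluates the
#' metric on each resample and reports the empirical percentile bounds
#' (2.5% and 97.5% by default, a 95% CI). Resamples on which the metric
#' is undefined (returns `NA` or errors, e.g. a one-class resample for
#' AUC) are redrawn and counted.
#'
#' @param metric_fn function of an index vector into the data (the caller
#'   closes over truth/score vectors), returning one number.
#' @param n number of documents to resample from.
#' @param n_boot bootstrap replicates (default 2000).
#' @param percentiles lower/upper percentile bounds.
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @return list with `point` (metric on the full data), `lower`, `upper`,
#'   and `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, n, n_boot = 2000,
                         percentiles = c(2.5, 97.5), seed = 1) {
  if (n < 1) {
    stop_littriage("bootstrap needs non-empty data",
                   "littriage_validation_error")
  }
  point <- metric_fn(seq_len(n))
  with_seed_local(seed, {
    vals <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(suppressWarnings(metric_fn(idx)),
                      error = function(e) NA_real_)
        if (!is.na(v)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100 * n_boot) {
          stop_littriage("metric undefined on virtually every resample",
                         "littriage_validation_error")
        }
      }
      vals[b] <- v
    }
    q <- stats::quantile(vals, percentiles / 100, names = FALSE, type = 7)
    list(point = point, lower = q[1], upper = q[2], n_redrawn = n_redrawn)
  })
}

#' McNemar paired comparison of two classifiers
#'
#' Operates on the per-document correctness of two classifiers evaluated
#' on the same test set. With `b` documents only classifier A got right
#' and `c` only classifier B, the exact two-sided binomial test is used
#' when `b + c < 25` and the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` otherwise (the switch point is
#' configurable).
#'
#' @param correct_a,correct_b logical vectors, per-document correctness.
#' @param exact_below use the exact test when `b + c` is below this.
#' @return list with `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b, exact_below = 25) {
  if (length(correct_a) != length(correct_b)) {
    stop_littriage("paired correctness vectors must have equal length",
                   "littriage_validation_error")
  }
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  nd <- b + c_
  if (nd == 0) {
    return(list(statistic = 0, p_value = 1, b = b, c = c_,
                method = "degenerate"))
  }
  if (nd < exact_below) {
    p <- min(1, 2 * stats::pbinom(min(b, c_), nd, 0.5))
    list(statistic = min(b, c_), p_value = p, b = b, c = c_,
         method = "exact binomial")
  } else {
    stat <- (abs(b - c_) - 1)^2 / nd
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = c_, method = "chi-square with continuity correction")
  }
}

#' Precision/recall curve for one target label
#'
#' Sweeps a decision threshold over the distinct predicted probabilities
#' of the target label in descending order; each threshold contributes
#' one (recall, precision) point. The final point always reaches
#' recall 1.
#'
#' @param y_true label vector.
#' @param label_scores per-document probability of the target label.
#' @param label the target label.
#' @return tibble with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(y_true, label_scores, label) {
  pos <- y_true == label
  if (!any(pos) || all(pos)) {
    stop_littriage("PR curve needs both positive and negative documents",
                   "littriage_validation_error")
  }
  thr <- sort(unique(label_scores), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    sel <- label_scores >= t
    c(recall = sum(sel & pos) / sum(pos),
      precision = if (any(sel)) sum(sel & pos) / sum(sel) else 1)
  }, numeric(2))
  tibble::tibble(threshold = thr, recall = pts["recall", ],
                 precision = pts["precision", ])
}
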
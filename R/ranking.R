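#' Ranking metrics over the top-k predicted sub-subclasses
#'
#' Each document's leaves are ranked by descending predicted probability
#' (ties resolved by `leaf_order`). With a single true label per document
#' the per-document quantities reduce to the rank `r` of the true label:
#' the document contributes `1/k` to P@k and 1 to R@k when `r <= k`, and
#' its average precision at k is `1/r` when `r <= k` (the relevant-set
#' size is 1), else 0. Consequently P@1 = R@1 = MAP@1, and R@k reaches 1
#' at `k` = number of leaves.
#'
#' @param y_true leaf label vector.
#' @param probs a [prob_matrix()].
#' @param tax the [taxonomy()].
#' @param ks integer vector of cutoffs, each at most the number of leaves.
#' @return tibble with columns `k`, `p_at_k`, `r_at_k`, `map_at_k`.
#' @export
ranking_metrics <- function(y_true, probs, tax, ks = c(1, 3)) {
  n_leaves <- length(tax$leaf_order)
  if (any(ks < 1) || any(ks > n_leaves)) {
    stop_littriage(sprintf("k must lie in [1, %d]", n_leaves),
                   "littriage_validation_error")
  }
  if (length(y_true) != nrow(probs)) {
    stop_littriage("y_true length must match the probability matrix",
                   "littriage_validation_error")
  }
  # rank of the true leaf per document; order() is stable, so equal
  # probabilities fall back to leaf_order
  true_col <- match(y_true, tax$leaf_order)
  ranks <- vapply(seq_len(nrow(probs)), function(i) {
    ord <- order(-probs[i, ])
    which(ord == true_col[i])
  }, integer(1))
  tibble::tibble(
    k = as.integer(ks),
    p_at_k = vapply(ks, function(k) mean((ranks <= k) / k), numeric(1)),
    r_at_k = vapply(ks, function(k) mean(ranks <= k), numeric(1)),
    map_at_k = vapply(ks, function(k) {
      mean(ifelse(ranks <= k, 1 / ranks, 0))
    }, numeric(1))
  )
}

#' Coverage/performance grid over voting configurations
#'
#' Evaluates the voting ensemble for every combination of vote-count
#' rule/threshold and per-vote probability threshold, reporting coverage
#' alongside precision, recall and F1 of one target label computed over
#' the decided (non-UNKNOWN) documents only. This exposes the trade
#' between annotating the whole collection and annotating a confident
#' subset with stricter rules.
#'
#' @param input an [ensemble_input()].
#' @param y_true label vector at `level` (or leaf ids, rolled up).
#' @param tax the [taxonomy()].
#' @param level taxonomy level.
#' @param target_label label whose one-vs-rest metrics are reported.
#' @param t_values static vote-count thresholds to scan.
#' @param t_v_values per-vote probability thresholds to scan.
#' @param rules subset of `"threshold"`, `"majority"`, `"unanimity"`;
#'   majority/unanimity are evaluated with dynamic per-document
#'   thresholds, `"threshold"` uses each static `t`.
#' @return tibble with one row per configuration: `rule`, `t`, `t_v`,
#'   `coverage`, `n_decided`, `precision`, `recall`, `f1` (metrics `NA`
#'   when nothing is decided).
#' @export
kvote_grid <- function(input, y_true, tax, level, target_label,
                       t_values = 3:5, t_v_values = c(0, 0.5, 0.9),
                       rules = c("threshold", "majority", "unanimity")) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  y_true <- ancestor_vec(tax, y_true, level)
  rules <- match.arg(rules, c("threshold", "majority", "unanimity"),
                     several.ok = TRUE)
  grid <- list()
  for (rule in rules) {
    ts <- if (rule == "threshold") t_values else NA_integer_
    for (t in ts) for (tv in t_v_values) {
      cfg <- if (rule == "threshold") {
        voting_config(t = t, t_v = tv, rule = "threshold")
      } else {
        voting_config(t_v = tv, rule = rule, dynamic = TRUE)
      }
      dec <- voting_ensemble(input, tax, level, cfg)
      decided <- dec$label != "UNKNOWN"
      row <- tibble::tibble(rule = rule, t = t, t_v = tv,
                            coverage = mean(decided),
                            n_decided = sum(decided),
                            precision = NA_real_, recall = NA_real_,
                            f1 = NA_real_)
      if (any(decided)) {
        cts <- contingency(y_true[decided], dec$label[decided], target_label)
        row$precision <- precision_score(cts)
        row$recall <- recall_score(cts)
        row$f1 <- f1_score(cts)
      }
      grid[[length(grid) + 1]] <- row
    }
  }
  do.call(rbind, grid)
}
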
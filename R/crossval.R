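#' End-to-end k-fold cross-validated evaluation
#'
#' Wires the pipeline: stratified fold assignment, reference-classifier
#' fitting per fold, leaf-probability prediction on the held-out test
#' set, and evaluation at the class, subclass and sub-subclass levels.
#' Final metrics are the unweighted mean over the k test folds (the test
#' sets are equal-sized by construction). A manifest records the
#' configuration, seed and taxonomy fingerprint so a rerun reproduces
#' the numbers bit for bit.
#'
#' @param corpus labeled corpus tibble (already filtered for
#'   completeness; see [filter_incomplete()]).
#' @param tax the [taxonomy()].
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @param baseline_config config list passed to [fit_baseline()].
#' @param levels taxonomy levels to evaluate.
#' @return list with `folds` (per-fold list of per-level metric lists),
#'   `pooled` (per-level tibble of micro/macro precision, recall and F1
#'   averaged over folds), and `manifest`.
#' @export
run_crossval <- function(corpus, tax, k = 5, seed = 1,
                         baseline_config = list(),
                         levels = TAXONOMY_LEVELS) {
  if (k < 2) {
    stop_littriage("cross-validation requires k >= 2",
                   "littriage_config_error")
  }
  levels <- match.arg(levels, TAXONOMY_LEVELS, several.ok = TRUE)
  validate_corpus(corpus, tax)
  if (anyNA(corpus$label)) {
    stop_littriage("run_crossval needs a fully labeled corpus",
                   "littriage_validation_error")
  }
  # test sets tile the corpus at 1/k; the rest splits 7:1 train:dev,
  # reproducing the 70/10/20 protocol at k = 5
  assignment <- kfold_split(corpus, k = k,
                            train_frac = (1 - 1 / k) * 7 / 8,
                            dev_frac = (1 - 1 / k) / 8,
                            test_frac = 1 / k, seed = seed)
  fold_reports <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    train <- fold_subset(corpus, assignment, f, "train")
    dev <- fold_subset(corpus, assignment, f, "dev")
    test <- fold_subset(corpus, assignment, f, "test")
    model <- fit_baseline(train, dev, tax, baseline_config)
    probs <- predict_proba(model, test, tax)
    per_level <- lapply(stats::setNames(levels, levels), function(lv) {
      truth <- ancestor(tax, test$label, lv)
      pred <- predict_label(probs, tax, lv)
      missing_lab <- setdiff(level_labels(tax, lv), unique(truth))
      if (length(missing_lab) > 0) {
        warning(sprintf("fold %d, level %s: label(s) absent from test: %s",
                        f, lv, paste(missing_lab, collapse = ", ")),
                call. = FALSE)
      }
      metrics_by_label(truth, pred, level_labels(tax, lv))
    })
    fold_reports[[f + 1L]] <- per_level
  }
  pooled <- do.call(rbind, lapply(levels, function(lv) {
    mic <- rowMeans(vapply(fold_reports, function(r) r[[lv]]$micro,
                           numeric(3)))
    mac <- rowMeans(vapply(fold_reports, function(r) r[[lv]]$macro,
                           numeric(3)))
    tibble::tibble(level = lv,
                   micro_precision = mic["precision"],
                   micro_recall = mic["recall"],
                   micro_f1 = mic["f1"],
                   macro_precision = mac["precision"],
                   macro_recall = mac["recall"],
                   macro_f1 = mac["f1"])
  }))
  manifest <- list(k = k, seed = seed, n_documents = nrow(corpus),
                   taxonomy_fingerprint = tax$fingerprint,
                   levels = levels, baseline_config = baseline_config,
                   package_version = as.character(utils::packageVersion("littriage")))
  list(folds = fold_reports, pooled = pooled, manifest = manifest)
}
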
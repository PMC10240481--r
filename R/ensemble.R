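#' Bundle member-model predictions for ensembling
#'
#' @param matrices list of [prob_matrix()] objects sharing document order
#'   and leaf order.
#' @param model_names optional character vector naming the members.
#' @return an object of class `ensemble_input`.
#' @export
ensemble_input <- function(matrices, model_names = NULL) {
  if (length(matrices) < 1) {
    stop_littriage("an ensemble needs at least one member matrix",
                   "littriage_validation_error")
  }
  ids <- rownames(matrices[[1]])
  cols <- colnames(matrices[[1]])
  for (m in matrices[-1]) {
    if (!identical(rownames(m), ids) || !identical(colnames(m), cols)) {
      stop_littriage("member matrices disagree on doc_ids or leaf order",
                     "littriage_validation_error")
    }
  }
  model_names <- model_names %||% sprintf("model_%d", seq_along(matrices))
  if (length(model_names) != length(matrices)) {
    stop_littriage("model_names length must match the number of matrices",
                   "littriage_validation_error")
  }
  structure(list(matrices = matrices, model_names = model_names,
                 doc_ids = ids),
            class = "ensemble_input")
}

#' @export
print.ensemble_input <- function(x, ...) {
  cat(sprintf("<ensemble_input> %d models x %d documents\n",
              length(x$matrices), length(x$doc_ids)))
  invisible(x)
}

#' Probability-sum ensemble
#'
#' Sums the member models' rolled-up probabilities per level label and
#' predicts the label with the highest summed score. Unlike voting, this
#' strategy always yields a unique prediction (ties, which have measure
#' zero for real probabilities, go to the earlier label in level order).
#' Scores are reported unnormalized, ranging over `[0, M]` for `M` models;
#' `normalize = TRUE` divides by `M`.
#'
#' @param input an [ensemble_input()].
#' @param tax the [taxonomy()].
#' @param level taxonomy level of the decision.
#' @param normalize divide summed scores by the number of models.
#' @return tibble with `doc_id`, `label`, `score` (the winning label's
#'   summed score); the full score matrix is attached as attribute
#'   `scores`.
#' @export
probability_sum_ensemble <- function(input, tax, level, normalize = FALSE) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  rolled <- lapply(input$matrices, function(m) rollup_matrix(tax, m, level))
  scores <- Reduce(`+`, rolled)
  if (normalize) scores <- scores / length(rolled)
  labs <- colnames(scores)
  win <- apply(scores, 1, which.max)
  out <- tibble::tibble(doc_id = input$doc_ids, label = labs[win],
                        score = scores[cbind(seq_along(win), win)])
  attr(out, "scores") <- scores
  out
}

#' Voting configuration
#'
#' @param t static vote-count threshold (ignored under a dynamic rule).
#' @param t_v per-vote probability threshold in `[0, 1]`: a member may
#'   only vote for its predicted label if that label's rolled-up
#'   probability reaches `t_v`; otherwise it abstains.
#' @param rule `"threshold"` (use `t`), `"majority"` or `"unanimity"`.
#' @param dynamic recompute majority/unanimity thresholds from the number
#'   of non-abstaining voters per document rather than the total number of
#'   models.
#' @return a `voting_config` list.
#' @export
voting_config <- function(t = 3L, t_v = 0, rule = c("threshold", "majority",
                                                    "unanimity"),
                          dynamic = FALSE) {
  rule <- match.arg(rule)
  if (t_v < 0 || t_v > 1) {
    stop_littriage("t_v must lie in [0, 1]", "littriage_config_error")
  }
  if (rule == "threshold" && t < 1) {
    stop_littriage("static vote threshold t must be >= 1",
                   "littriage_config_error")
  }
  structure(list(t = as.integer(t), t_v = t_v, rule = rule,
                 dynamic = isTRUE(dynamic)),
            class = "voting_config")
}

#' Cast per-model votes with a probability threshold
#'
#' Each member votes for its rolled-up argmax label iff that label's
#' probability is at least `t_v`; otherwise it abstains (`NA`). At the
#' binary class level `t_v = 0.5` can never silence a member, since the
#' larger of two probabilities is at least 0.5.
#'
#' @param input an [ensemble_input()].
#' @param tax the [taxonomy()].
#' @param level taxonomy level.
#' @param t_v probability threshold in `[0, 1]`.
#' @return character matrix, documents x models; `NA` marks abstention.
#' @export
cast_votes <- function(input, tax, level, t_v = 0) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  if (t_v < 0 || t_v > 1) {
    stop_littriage("t_v must lie in [0, 1]", "littriage_config_error")
  }
  votes <- vapply(input$matrices, function(m) {
    rolled <- rollup_matrix(tax, m, level)
    labs <- colnames(rolled)
    win <- apply(rolled, 1, which.max)
    top <- rolled[cbind(seq_along(win), win)]
    ifelse(top >= t_v, labs[win], NA_character_)
  }, character(length(input$doc_ids)))
  votes <- matrix(votes, nrow = length(input$doc_ids),
                  dimnames = list(input$doc_ids, input$model_names))
  votes
}

#' Voting ensemble with abstention
#'
#' Members vote via [cast_votes()]; a label is decided when its tally is
#' the unique maximum and reaches the effective threshold — the static `t`
#' under `rule = "threshold"`, or, under dynamic rules, a threshold
#' recomputed per document from the `v` non-abstaining voters
#' (majority `floor(v/2) + 1`, unanimity `v`). Tied top tallies,
#' insufficient votes, or all-abstain documents yield the distinguished
#' `UNKNOWN` outcome.
#'
#' @param input an [ensemble_input()].
#' @param tax the [taxonomy()].
#' @param level taxonomy level.
#' @param config a [voting_config()].
#' @return tibble of class `ensemble_decision` with `doc_id`, `label`
#'   (level label id or `"UNKNOWN"`), `n_votes` (non-abstaining voters),
#'   `top_tally`, `threshold` (effective per-document threshold); the raw
#'   vote matrix is attached as attribute `votes`.
#' @export
voting_ensemble <- function(input, tax, level, config = voting_config()) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  m_models <- length(input$matrices)
  if (config$rule == "threshold" && !config$dynamic && config$t > m_models) {
    stop_littriage(sprintf("static threshold t=%d exceeds the %d models",
                           config$t, m_models),
                   "littriage_config_error")
  }
  votes <- cast_votes(input, tax, level, config$t_v)
  labs <- level_labels(tax, level)
  n <- nrow(votes)
  label <- character(n); n_votes <- integer(n)
  top_tally <- integer(n); threshold <- integer(n)
  for (i in seq_len(n)) {
    cast <- votes[i, !is.na(votes[i, ])]
    v <- length(cast)
    n_votes[i] <- v
    thr <- if (config$dynamic || config$rule != "threshold") {
      switch(config$rule,
             threshold = config$t,
             majority = if (config$dynamic) v %/% 2L + 1L else m_models %/% 2L + 1L,
             unanimity = if (config$dynamic) v else m_models)
    } else config$t
    threshold[i] <- thr
    if (v == 0) {
      label[i] <- "UNKNOWN"; top_tally[i] <- 0L
      next
    }
    tally <- table(factor(cast, levels = labs))
    best <- max(tally)
    top_tally[i] <- as.integer(best)
    winners <- names(tally)[tally == best]
    label[i] <- if (length(winners) == 1 && best >= thr) winners else "UNKNOWN"
  }
  out <- tibble::tibble(doc_id = input$doc_ids, label = label,
                        n_votes = n_votes, top_tally = top_tally,
                        threshold = threshold)
  class(out) <- c("ensemble_decision", class(out))
  attr(out, "votes") <- votes
  out
}

#' Fraction of documents the ensemble decided
#'
#' @param decisions an `ensemble_decision` tibble (or any data frame with
#'   a `label` column using the `"UNKNOWN"` literal for abstention).
#' @return coverage in `[0, 1]`.
#' @export
coverage <- function(decisions) {
  if (nrow(decisions) == 0) {
    stop_littriage("coverage is undefined for an empty decision set",
                   "littriage_validation_error")
  }
  mean(decisions$label != "UNKNOWN")
}
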
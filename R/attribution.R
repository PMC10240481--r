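#' Integrated gradients for a differentiable scorer
#'
#' Attributes a scorer's output to each input feature along the straight
#' line from a baseline input to the input of interest:
#' `attribution_i = (x_i - baseline_i) * mean_j grad_i(baseline + a_j (x - baseline))`
#' with midpoint path points `a_j = (j - 1/2)/steps`. For a linear scorer
#' this is exact at any number of steps; in general the attributions sum
#' to `scorer(x) - scorer(baseline)` up to the Riemann discretization
#' error (the completeness property).
#'
#' @param scorer a list with functions `value(x)` (scalar score of the
#'   target label) and `grad(x)` (gradient vector), e.g. from
#'   [linear_scorer()] or [baseline_scorer()].
#' @param x numeric feature vector.
#' @param baseline reference feature vector of the same length; the
#'   all-zero vector (an empty document) by default.
#' @param steps number of midpoint Riemann points.
#' @return numeric attribution vector, one entry per feature.
#' @export
integrated_gradients <- function(scorer, x, baseline = NULL, steps = 50) {
  baseline <- baseline %||% rep(0, length(x))
  if (length(baseline) != length(x)) {
    stop_littriage("x and baseline must have the same dimension",
                   "littriage_validation_error")
  }
  delta <- x - baseline
  acc <- rep(0, length(x))
  for (j in seq_len(steps)) {
    a <- (j - 0.5) / steps
    g <- scorer$grad(baseline + a * delta)
    if (any(!is.finite(g))) {
      stop_littriage(sprintf("non-finite gradient at path step %d", j),
                     "littriage_numeric_error")
    }
    acc <- acc + g
  }
  delta * acc / steps
}

#' Scorers for attribution
#'
#' `linear_scorer(w, b)` wraps the affine map `w . x + b`;
#' `baseline_scorer(model, target, tax, level)` exposes the fitted
#' reference classifier's rolled-up probability of a target label (at any
#' taxonomy level) as a differentiable function of the token-count
#' vector, with an analytic softmax gradient.
#'
#' @param w weight vector.
#' @param b intercept.
#' @return a scorer list with `value` and `grad` functions.
#' @export
linear_scorer <- function(w, b = 0) {
  list(value = function(x) sum(w * x) + b,
       grad = function(x) w)
}

#' @rdname linear_scorer
#' @param model a fitted `baseline_model`.
#' @param target label id whose probability is scored.
#' @param tax the [taxonomy()].
#' @param level taxonomy level of `target`.
#' @export
baseline_scorer <- function(model, target, tax, level = "subclass") {
  level <- match.arg(level, TAXONOMY_LEVELS)
  cf <- baseline_coefficients(model)
  in_target <- if (level == "sub-subclass") {
    model$classes == target
  } else {
    ancestor(tax, model$classes, level) == target
  }
  if (!any(in_target)) {
    stop_littriage(sprintf("no observed leaf rolls up to '%s'", target),
                   "littriage_lookup_error")
  }
  prob_fn <- function(x) {
    z <- as.numeric(x %*% cf$W) + cf$b
    z <- z - max(z)
    p <- exp(z) / sum(exp(z))
    p
  }
  list(
    value = function(x) sum(prob_fn(x)[in_target]),
    # d/dx_i sum_{c in T} p_c = sum_c p_c (W_ic - sum_k p_k W_ik)
    grad = function(x) {
      p <- prob_fn(x)
      pbar <- as.numeric(cf$W %*% p)
      as.numeric(cf$W[, in_target, drop = FALSE] %*% p[in_target]) -
        sum(p[in_target]) * pbar
    }
  )
}

#' Token attributions of one document under the reference classifier
#'
#' Runs integrated gradients on the document's token-count vector against
#' an empty-document baseline, targeting the rolled-up probability of a
#' label. The count-feature attribution of each vocabulary word is split
#' evenly over its occurrences so that occurrence-level means reproduce
#' the feature attribution.
#'
#' @param model a fitted `baseline_model`.
#' @param text the composed input text of one document (see
#'   [compose_input_text()]).
#' @param target label id to attribute towards.
#' @param tax the [taxonomy()].
#' @param level taxonomy level of `target`.
#' @param steps integrated-gradient path points.
#' @param doc_id id recorded in the output.
#' @return tibble with `doc_id`, `token_index`, `token`,
#'   `is_continuation` (always `FALSE` for word-count features), `score`.
#' @export
attribute_document <- function(model, text, target, tax,
                               level = "subclass", steps = 50,
                               doc_id = "doc") {
  toks <- tokenize_text(text)[[1]]
  x <- as.numeric(table(factor(toks, levels = model$vocab)))
  scorer <- baseline_scorer(model, target, tax, level)
  attr_vec <- integrated_gradients(scorer, x, steps = steps)
  names(attr_vec) <- model$vocab
  in_vocab <- toks %in% model$vocab
  idx <- which(in_vocab)
  tok <- toks[in_vocab]
  per_occ <- attr_vec[tok] / as.numeric(table(factor(tok, levels = model$vocab))[tok])
  tibble::tibble(doc_id = doc_id, token_index = idx, token = tok,
                 is_continuation = FALSE, score = as.numeric(per_occ))
}

#' Merge sub-word attributions into word scores
#'
#' Transformer tokenizers split words into sub-words (a continuation
#' piece is flagged, e.g. `"Stu"` + `"#dy"` for "Study"); the word's
#' score is the mean of its sub-word scores. Token rows must be ordered
#' by `token_index` within each document and continuation pieces must
#' follow a head piece.
#'
#' @param attributions tibble with columns `doc_id`, `token_index`,
#'   `token`, `is_continuation`, `score` (as read by
#'   [read_token_attributions()]).
#' @param strip_marker regular expression removed from the front of
#'   continuation pieces when gluing the surface form (default `"^#+"`).
#' @return tibble with `doc_id`, `word_index`, `word`, `score` (mean of
#'   constituent sub-word scores).
#' @export
word_scores_from_subwords <- function(attributions, strip_marker = "^#+") {
  out <- list()
  for (d in unique(attributions$doc_id)) {
    rows <- attributions[attributions$doc_id == d, , drop = FALSE]
    rows <- rows[order(rows$token_index), , drop = FALSE]
    if (nrow(rows) > 0 && rows$is_continuation[1]) {
      stop_littriage(sprintf(
        "document '%s' starts with a continuation sub-word", d),
        "littriage_format_error")
    }
    word_id <- cumsum(!rows$is_continuation)
    words <- vapply(split(seq_len(nrow(rows)), word_id), function(i) {
      pieces <- rows$token[i]
      pieces[-1] <- sub(strip_marker, "", pieces[-1])
      paste(pieces, collapse = "")
    }, character(1))
    scores <- vapply(split(rows$score, word_id), mean, numeric(1))
    out[[d]] <- tibble::tibble(doc_id = d,
                               word_index = seq_along(words),
                               word = unname(words),
                               score = unname(scores))
  }
  do.call(rbind, out)
}

#' Aggregate word scores into lemma-level impacts
#'
#' Words are lowercased and lemmatized, and every occurrence across the
#' analyzed document set contributes its score to the lemma's arithmetic
#' mean — so "simulation" and "simulations" pool their evidence under
#' the lemma "simulation".
#'
#' @param word_scores tibble with columns `word`, `score` (e.g. from
#'   [word_scores_from_subwords()] or [attribute_document()], whose
#'   `token` column is accepted as `word`).
#' @param lemmatizer deterministic `function(character) -> character`;
#'   defaults to [default_lemmatizer()].
#' @return tibble with `lemma`, `mean_score`, `occurrences`, sorted by
#'   `mean_score` descending.
#' @export
aggregate_lemma_scores <- function(word_scores, lemmatizer = default_lemmatizer) {
  w <- if ("word" %in% names(word_scores)) word_scores$word else
    word_scores$token
  lemma <- lemmatizer(tolower(w))
  agg <- tapply(word_scores$score, lemma, mean)
  occ <- tapply(word_scores$score, lemma, length)
  out <- tibble::tibble(lemma = names(agg),
                        mean_score = as.numeric(agg),
                        occurrences = as.integer(occ))
  out[order(-out$mean_score, out$lemma), , drop = FALSE]
}

#' Rule-based English lemmatizer
#'
#' A small deterministic suffix stripper (plural and inflection rules:
#' `ies -> y`, `sses -> ss`, trailing `s` after consonants, `ing`/`ed`
#' left untouched to avoid over-stemming). Pluggable: any
#' string-to-string map can replace it in [aggregate_lemma_scores()].
#'
#' @param words lowercased character vector.
#' @return character vector of lemmas.
#' @export
default_lemmatizer <- function(words) {
  out <- words
  ies <- grepl("[a-z]ies$", out)
  out[ies] <- sub("ies$", "y", out[ies])
  sses <- grepl("sses$", out)
  out[sses] <- sub("es$", "", out[sses])
  es_sib <- grepl("(x|z|ch|sh)es$", out)
  out[es_sib] <- sub("es$", "", out[es_sib])
  plain_s <- grepl("[a-rt-z]s$", out) & !grepl("(ss|us|is)$", out) &
    !ies & !sses & !es_sib
  out[plain_s] <- sub("s$", "", out[plain_s])
  out
}

#' Top positive-impact words
#'
#' Filters lemma impacts to those seen at least `min_occurrences` times
#' with a positive mean score, then ranks by mean score (ties
#' alphabetically) and keeps the first `k`.
#'
#' @param impacts tibble from [aggregate_lemma_scores()].
#' @param k list length (default 20).
#' @param min_occurrences minimum occurrence count (default 5).
#' @return tibble with `rank`, `lemma`, `mean_score`, `occurrences`;
#'   possibly fewer than `k` rows.
#' @export
top_impact_words <- function(impacts, k = 20, min_occurrences = 5) {
  keep <- impacts$occurrences >= min_occurrences & impacts$mean_score > 0
  sel <- impacts[keep, , drop = FALSE]
  sel <- sel[order(-sel$mean_score, sel$lemma), , drop = FALSE]
  sel <- utils::head(sel, k)
  tibble::tibble(rank = seq_len(nrow(sel)), lemma = sel$lemma,
                 mean_score = sel$mean_score,
                 occurrences = sel$occurrences)
}

#' Token-attribution file IO
#'
#' Tab-separated columns `doc_id`, `token_index`, `token`,
#' `is_continuation` (0/1), `score` — the exchange format for ingesting
#' precomputed transformer attributions.
#'
#' @param attributions tibble in that layout.
#' @param path file path.
#' @export
write_token_attributions <- function(attributions, path) {
  df <- attributions[, c("doc_id", "token_index", "token",
                         "is_continuation", "score")]
  df$is_continuation <- as.integer(df$is_continuation)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_token_attributions
#' @export
read_token_attributions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_continuation <- as.logical(df$is_continuation)
  tibble::as_tibble(df)
}
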
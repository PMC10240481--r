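#' Synthetic corpus generator configuration
#'
#' The generator emulates the structure of an annotated living-evidence
#' snapshot: heavily imbalanced sub-subclass proportions (by default the
#' packaged collection's leaf frequencies, 0.5%-27.6%), three free-text
#' fields per record, and class-conditional lexical signal — each leaf
#' owns a small signature vocabulary, and each content token is drawn
#' from it with probability `signal_strength`, otherwise from a shared
#' background vocabulary.
#'
#' @param tax a [taxonomy()] (default [default_taxonomy()]).
#' @param n_docs number of records.
#' @param leaf_proportions distribution over `tax$leaf_order`; defaults
#'   to the packaged collection's proportions.
#' @param signature_tokens_per_leaf size of each leaf's private
#'   vocabulary.
#' @param signal_strength probability in `[0, 1]` that a content token is
#'   a signature token of the record's leaf.
#' @param background_vocab_size shared vocabulary size.
#' @param title_tokens,abstract_tokens integer ranges (length-2 vectors)
#'   for the number of tokens per field.
#' @param source_set source strings sampled uniformly.
#' @param seed integer seed.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(tax = default_taxonomy(), n_docs = 1000,
                          leaf_proportions = NULL,
                          signature_tokens_per_leaf = 5,
                          signal_strength = 0.7,
                          background_vocab_size = 500,
                          title_tokens = c(5, 15),
                          abstract_tokens = c(40, 120),
                          source_set = c("PubMed", "Embase", "medRxiv",
                                         "bioRxiv"),
                          seed = 1) {
  if (is.null(leaf_proportions)) {
    cts <- default_leaf_counts()
    if (!identical(names(cts), tax$leaf_order)) {
      stop_littriage("leaf_proportions required for a non-default taxonomy",
                     "littriage_config_error")
    }
    leaf_proportions <- cts / sum(cts)
  }
  if (length(leaf_proportions) != length(tax$leaf_order)) {
    stop_littriage("leaf_proportions length must match the taxonomy leaves",
                   "littriage_config_error")
  }
  if (any(leaf_proportions < 0) || abs(sum(leaf_proportions) - 1) > 1e-9) {
    stop_littriage("leaf_proportions must be a distribution",
                   "littriage_config_error")
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop_littriage("signal_strength must lie in [0, 1]",
                   "littriage_config_error")
  }
  structure(list(tax = tax, n_docs = n_docs,
                 leaf_proportions = stats::setNames(as.numeric(leaf_proportions),
                                                    tax$leaf_order),
                 signature_tokens_per_leaf = signature_tokens_per_leaf,
                 signal_strength = signal_strength,
                 background_vocab_size = background_vocab_size,
                 title_tokens = title_tokens,
                 abstract_tokens = abstract_tokens,
                 source_set = source_set, seed = seed),
            class = "corpus_config")
}

#' Generate a labeled synthetic corpus
#'
#' @param config a [corpus_config()].
#' @return a labeled corpus tibble (`doc_id`, `title`, `abstract`,
#'   `source`, `label`), reproducible from the config seed.
#' @export
generate_corpus <- function(config) {
  tax <- config$tax
  if (length(config$leaf_proportions) == 0) {
    stop_littriage("empty leaf proportions", "littriage_config_error")
  }
  with_seed_local(config$seed, {
    leaves <- tax$leaf_order
    sig_vocab <- lapply(stats::setNames(leaves, leaves), function(l) {
      # single-token signatures: must survive tokenization unsplit
      sprintf("%ssig%02d", gsub("[^a-z0-9]+", "", l),
              seq_len(config$signature_tokens_per_leaf))
    })
    bg_vocab <- sprintf("bgword%04d", seq_len(config$background_vocab_size))
    labels <- sample(leaves, config$n_docs, replace = TRUE,
                     prob = config$leaf_proportions)
    field <- function(lab, n_range) {
      n <- sample(seq(n_range[1], n_range[2]), 1)
      from_sig <- stats::runif(n) < config$signal_strength
      toks <- character(n)
      if (any(from_sig)) {
        toks[from_sig] <- sample(sig_vocab[[lab]], sum(from_sig),
                                 replace = TRUE)
      }
      if (any(!from_sig)) {
        toks[!from_sig] <- sample(bg_vocab, sum(!from_sig), replace = TRUE)
      }
      paste(toks, collapse = " ")
    }
    tibble::tibble(
      doc_id = sprintf("doc%06d", seq_len(config$n_docs)),
      title = vapply(labels, field, character(1), config$title_tokens),
      abstract = vapply(labels, field, character(1), config$abstract_tokens),
      source = sample(config$source_set, config$n_docs, replace = TRUE),
      label = labels
    )
  })
}

#' Prediction simulator configuration
#'
#' Simulates the leaf-probability outputs of a committee of imperfect
#' classifiers over known true labels, so ensemble and evaluation code
#' can be exercised at any scale. Per document, a latent "hard document"
#' draw shared across models (mixing weight `agreement`) correlates the
#' members' error events; an erring model's modal label is a confusable
#' leaf, preferring leaves of the same subclass 3:1 over other leaves
#' (reproducing the intra-subclass confusion structure typical of
#' study-design classifiers). Rows are Dirichlet-distributed with weight
#' `concentration` on the modal leaf and 1 elsewhere, so a single knob
#' controls how often per-vote probability thresholds trigger
#' abstention.
#'
#' @param n_models committee size (default 5).
#' @param per_model_accuracy scalar or length-`n_models` vector in
#'   `(0, 1]`: each member's probability of a correct modal label.
#' @param agreement correlation in `[0, 1]` of the members' error events
#'   (1 = all err on exactly the same documents).
#' @param concentration positive Dirichlet weight of the modal leaf.
#' @param seed integer seed.
#' @return a `prediction_config` list.
#' @export
prediction_config <- function(n_models = 5, per_model_accuracy = 0.8,
                              agreement = 0.3, concentration = 20,
                              seed = 1) {
  acc <- rep_len(per_model_accuracy, n_models)
  if (any(acc <= 0) || any(acc > 1)) {
    stop_littriage("per_model_accuracy must lie in (0, 1]",
                   "littriage_config_error")
  }
  if (agreement < 0 || agreement > 1) {
    stop_littriage("agreement must lie in [0, 1]", "littriage_config_error")
  }
  if (concentration <= 0) {
    stop_littriage("concentration must be positive",
                   "littriage_config_error")
  }
  structure(list(n_models = n_models, per_model_accuracy = acc,
                 agreement = agreement, concentration = concentration,
                 seed = seed),
            class = "prediction_config")
}

#' Simulate correlated multi-model probability predictions
#'
#' @param truth character vector of true leaf labels.
#' @param tax the [taxonomy()].
#' @param config a [prediction_config()].
#' @param doc_ids optional document ids (defaults to `sim000001`, ...).
#' @return an [ensemble_input()] of `n_models` probability matrices.
#' @details Error events: per document a shared uniform draw `u` and per
#'   model a fresh draw `u_m`; model `m` errs when its effective draw
#'   (`u` with probability `agreement`, else `u_m`) exceeds its
#'   accuracy's complement — marginally each model errs at rate
#'   `1 - accuracy_m` at every `agreement`.
#' @export
simulate_predictions <- function(truth, tax, config = prediction_config(),
                                 doc_ids = NULL) {
  n <- length(truth)
  if (!all(truth %in% tax$leaf_order)) {
    stop_littriage("truth labels must be taxonomy leaves",
                   "littriage_validation_error")
  }
  doc_ids <- doc_ids %||% sprintf("sim%06d", seq_len(n))
  leaves <- tax$leaf_order
  k <- length(leaves)
  sub_of <- ancestor(tax, leaves, "subclass")
  with_seed_local(config$seed, {
    u_shared <- stats::runif(n)
    use_shared <- matrix(stats::runif(n * config$n_models) < config$agreement,
                         n, config$n_models)
    matrices <- vector("list", config$n_models)
    for (m in seq_len(config$n_models)) {
      u_own <- stats::runif(n)
      u_eff <- ifelse(use_shared[, m], u_shared, u_own)
      err <- u_eff > config$per_model_accuracy[m]
      modal <- truth
      if (any(err)) {
        modal[err] <- vapply(which(err), function(i) {
          w <- ifelse(sub_of == sub_of[match(truth[i], leaves)], 3, 1)
          w[match(truth[i], leaves)] <- 0
          sample(leaves, 1, prob = w)
        }, character(1))
      }
      # Dirichlet(concentration on modal, 1 elsewhere) via gamma draws
      g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
      g[cbind(seq_len(n), match(modal, leaves))] <-
        stats::rgamma(n, shape = config$concentration)
      p <- g / rowSums(g)
      matrices[[m]] <- prob_matrix(p, doc_ids, tax)
    }
    ensemble_input(matrices, sprintf("sim_model_%d", seq_len(config$n_models)))
  })
}
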
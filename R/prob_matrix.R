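#' Probability matrices over taxonomy leaves
#'
#' A probability matrix holds one predicted distribution over the
#' taxonomy's sub-subclasses per document: rows are documents (rownames =
#' `doc_id`), columns follow the taxonomy's `leaf_order` exactly, and every
#' row sums to 1 within `1e-6` (the sub-subclasses are mutually exclusive).
#'
#' @param values numeric matrix, documents x leaves.
#' @param doc_ids character vector of document ids (row order).
#' @param tax the [taxonomy()] whose `leaf_order` the columns follow.
#' @return the validated matrix with `doc_ids` as rownames, `leaf_order`
#'   as colnames and attribute `taxonomy_fingerprint`.
#' @export
prob_matrix <- function(values, doc_ids, tax) {
  values <- as.matrix(values)
  if (nrow(values) != length(doc_ids)) {
    stop_littriage("doc_ids length does not match matrix rows",
                   "littriage_validation_error")
  }
  if (ncol(values) != length(tax$leaf_order)) {
    stop_littriage("matrix columns do not match taxonomy leaf_order",
                   "littriage_validation_error")
  }
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), tax$leaf_order)) {
    stop_littriage("matrix column names disagree with taxonomy leaf_order",
                   "littriage_validation_error")
  }
  if (nrow(values) > 0) {
    if (any(values < 0)) {
      stop_littriage("probabilities must be nonnegative",
                     "littriage_validation_error")
    }
    off <- abs(rowSums(values) - 1)
    if (any(off > 1e-6)) {
      stop_littriage(sprintf(
        "row(s) not summing to 1 within 1e-6 (worst deviation %.2e)",
        max(off)), "littriage_validation_error")
    }
  }
  dimnames(values) <- list(doc_ids, tax$leaf_order)
  attr(values, "taxonomy_fingerprint") <- tax$fingerprint
  values
}

#' Write / read a probability matrix as delimited text
#'
#' Tab-separated, first column `doc_id`, then one column per leaf id in
#' `leaf_order`. Reading checks the header against the taxonomy and
#' refuses silently re-ordered or foreign columns.
#'
#' @param m a [prob_matrix()].
#' @param path file path.
#' @export
write_prob_matrix <- function(m, path) {
  df <- data.frame(doc_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prob_matrix
#' @param tax the active [taxonomy()].
#' @export
read_prob_matrix <- function(path, tax) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "doc_id")) {
    stop_littriage("probability matrix file must start with a doc_id column",
                   "littriage_format_error")
  }
  if (!identical(names(df)[-1], tax$leaf_order)) {
    stop_littriage(
      "probability matrix header does not match the taxonomy leaf_order",
      "littriage_format_error")
  }
  prob_matrix(as.matrix(df[, -1, drop = FALSE]), df$doc_id, tax)
}

#' Predicted label at a taxonomy level
#'
#' Rolls every row of a probability matrix up to the requested level and
#' takes the most probable label; exact ties go to the earlier label in
#' the level's declaration order, making predictions reproducible.
#'
#' @param probs a [prob_matrix()].
#' @param tax the [taxonomy()].
#' @param level `"class"`, `"subclass"` or `"sub-subclass"`.
#' @return character vector of level-label ids, one per document.
#' @export
predict_label <- function(probs, tax, level) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  if (nrow(probs) == 0) return(character(0))
  rolled <- rollup_matrix(tax, probs, level)
  labs <- colnames(rolled)
  labs[apply(rolled, 1, which.max)]
}
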
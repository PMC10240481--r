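#' Nested study-design taxonomies
#'
#' A taxonomy is a three-level nested label space: sub-subclasses (the
#' leaves) partition into subclasses, which partition into classes. All
#' probability matrices produced by classifiers in this package are indexed
#' by the taxonomy's fixed `leaf_order`, and coarser-level predictions are
#' obtained by summing leaf probabilities over each ancestor's descendants.
#'
#' @param nodes a data frame with columns `id`, `name`, `level`
#'   (one of `"class"`, `"subclass"`, `"sub-subclass"`) and `parent`
#'   (`NA` for class-level nodes).
#' @param name optional display name for the taxonomy.
#' @return An object of class `taxonomy`: a list with elements `nodes`
#'   (validated node table), `leaf_order` (sub-subclass ids in input order),
#'   `name`, and `fingerprint` (stable hash of the node structure, used to
#'   detect taxonomy mismatches between artifacts).
#' @details Validation enforces unique ids, a parent for every non-class
#'   node, class parents for subclasses and subclass parents for leaves;
#'   violations name the offending node.
#' @seealso [load_taxonomy()], [default_taxonomy()], [roll_up_distribution()]
#' @export
taxonomy <- function(nodes, name = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("id", "name", "level")
  if (!all(req %in% names(nodes))) {
    stop_littriage(sprintf(
      "taxonomy nodes need columns %s", paste(req, collapse = ", ")
    ), "littriage_validation_error")
  }
  if (is.null(nodes$parent)) nodes$parent <- NA_character_
  nodes$parent[!is.na(nodes$parent) & nodes$parent == ""] <- NA_character_
  nodes <- nodes[, c("id", "name", "level", "parent",
                     intersect("alias", names(nodes)))]

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) {
    stop_littriage(sprintf("duplicate node id(s): %s",
                           paste(unique(dup), collapse = ", ")),
                   "littriage_validation_error")
  }
  bad_level <- setdiff(unique(nodes$level), TAXONOMY_LEVELS)
  if (length(bad_level) > 0) {
    stop_littriage(sprintf("unknown level(s): %s",
                           paste(bad_level, collapse = ", ")),
                   "littriage_validation_error")
  }
  parent_level <- c("subclass" = "class", "sub-subclass" = "subclass")
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    if (nd$level == "class") {
      if (!is.na(nd$parent)) {
        stop_littriage(sprintf("class node '%s' must not have a parent", nd$id),
                       "littriage_validation_error")
      }
      next
    }
    if (is.na(nd$parent)) {
      stop_littriage(sprintf("node '%s' (%s) has no parent", nd$id, nd$level),
                     "littriage_validation_error")
    }
    p <- nodes[nodes$id == nd$parent, ]
    if (nrow(p) == 0) {
      stop_littriage(sprintf("node '%s' references missing parent '%s'",
                             nd$id, nd$parent),
                     "littriage_validation_error")
    }
    if (p$level != parent_level[[nd$level]]) {
      stop_littriage(sprintf(
        "node '%s' (%s) has parent '%s' of level %s; expected %s",
        nd$id, nd$level, p$id, p$level, parent_level[[nd$level]]
      ), "littriage_validation_error")
    }
  }

  leaf_order <- nodes$id[nodes$level == "sub-subclass"]
  canon <- paste(nodes$id, nodes$level, ifelse(is.na(nodes$parent), "", nodes$parent),
                 sep = ":", collapse = ";")
  structure(
    list(nodes = nodes, leaf_order = leaf_order,
         name = name %||% "taxonomy", fingerprint = fnv1a32(canon)),
    class = "taxonomy"
  )
}

TAXONOMY_LEVELS <- c("class", "subclass", "sub-subclass")

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %s: %d classes, %d subclasses, %d sub-subclasses [%s]\n",
              x$name,
              sum(x$nodes$level == "class"),
              sum(x$nodes$level == "subclass"),
              length(x$leaf_order),
              x$fingerprint))
  invisible(x)
}

#' Read a taxonomy from a declarative JSON document
#'
#' The document holds a `nodes` array of `{id, name, level, parent}` objects;
#' sub-subclass entries fix `leaf_order` by their order of appearance.
#' [write_taxonomy()] round-trips the same structure.
#'
#' @param path path to a taxonomy JSON file.
#' @return a validated [taxonomy()].
#' @export
load_taxonomy <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$nodes)) {
    stop_littriage("taxonomy document has no 'nodes' entry",
                   "littriage_format_error")
  }
  taxonomy(doc$nodes, name = doc$name)
}

#' @rdname load_taxonomy
#' @param tax a [taxonomy()].
#' @export
write_taxonomy <- function(tax, path) {
  nodes <- tax$nodes
  recs <- lapply(seq_len(nrow(nodes)), function(i) {
    r <- as.list(nodes[i, ])
    r <- r[!vapply(r, function(v) is.na(v) || identical(v, ""), logical(1))]
    r
  })
  jsonlite::write_json(list(name = tax$name, nodes = recs), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The packaged default taxonomy
#'
#' Loads the COAP living-evidence study-design scheme shipped with the
#' package: 22 sub-subclasses nested into the EPI, BASIC and OTHER
#' subclasses, themselves nested into the ORIGINAL and NON-ORIGINAL classes.
#'
#' @return a [taxonomy()] with 22 leaves.
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "coap_taxonomy.json",
                            package = "littriage", mustWork = TRUE))
}

#' Document counts of the default annotated collection
#'
#' Per-leaf document counts of the 6365-publication COAP snapshot the
#' default taxonomy was built for, in `leaf_order`. Useful as realistic
#' class-imbalance weights for the synthetic corpus generator.
#'
#' @return named integer vector over the default taxonomy's leaves.
#' @export
default_leaf_counts <- function() {
  df <- utils::read.csv(system.file("extdata", "coap_leaf_counts.csv",
                                    package = "littriage", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$count), df$leaf_id)
}

#' Labels of a taxonomy level
#'
#' @param tax a [taxonomy()].
#' @param level `"class"`, `"subclass"` or `"sub-subclass"`.
#' @return character vector of node ids at the level, in declaration order
#'   (for sub-subclass this is `leaf_order`).
#' @export
level_labels <- function(tax, level) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  tax$nodes$id[tax$nodes$level == level]
}

#' Ancestor of a leaf at a coarser level
#'
#' @param tax a [taxonomy()].
#' @param leaf_id a sub-subclass id.
#' @param level target level; `"sub-subclass"` returns the leaf itself.
#' @return the unique ancestor id at `level`.
#' @export
ancestor <- function(tax, leaf_id, level) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  vapply(leaf_id, function(lf) {
    if (!lf %in% tax$leaf_order) {
      stop_littriage(sprintf("unknown leaf '%s'", lf), "littriage_lookup_error")
    }
    cur <- lf
    cur_level <- "sub-subclass"
    while (cur_level != level) {
      cur <- tax$nodes$parent[tax$nodes$id == cur]
      cur_level <- tax$nodes$level[tax$nodes$id == cur]
    }
    cur
  }, character(1), USE.NAMES = FALSE)
}

# named list: level label -> character vector of descendant leaf ids
descendant_leaves <- function(tax, level) {
  labs <- level_labels(tax, level)
  anc <- ancestor(tax, tax$leaf_order, level)
  lapply(stats::setNames(labs, labs), function(l) tax$leaf_order[anc == l])
}

#' Roll leaf probabilities up to a coarser level
#'
#' Each coarser label's probability is the sum of the predicted
#' probabilities of its descendant sub-subclasses, so a document's class
#' probability is the total probability of all study designs mapped to that
#' class. The leaf vector must be a probability distribution.
#'
#' @param tax a [taxonomy()].
#' @param leaf_probs numeric vector over `tax$leaf_order` (or a matrix with
#'   one row per document and columns in `leaf_order`).
#' @param level target level.
#' @return vector (or matrix) of probabilities over [level_labels()].
#' @export
roll_up_distribution <- function(tax, leaf_probs, level) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  mat <- if (is.matrix(leaf_probs)) leaf_probs else
    matrix(leaf_probs, nrow = 1, dimnames = list(NULL, names(leaf_probs)))
  if (ncol(mat) != length(tax$leaf_order)) {
    stop_littriage("leaf_probs length does not match taxonomy leaf_order",
                   "littriage_contract_error")
  }
  if (any(mat < 0)) {
    stop_littriage("leaf_probs has negative entries",
                   "littriage_contract_error")
  }
  if (any(abs(rowSums(mat) - 1) > 1e-9)) {
    stop_littriage("leaf_probs rows must sum to 1 (tolerance 1e-9)",
                   "littriage_contract_error")
  }
  out <- rollup_matrix(tax, mat, level)
  if (is.matrix(leaf_probs)) out else out[1, ]
}

# unchecked workhorse: sums leaf columns into level-label columns
rollup_matrix <- function(tax, mat, level) {
  if (level == "sub-subclass") {
    colnames(mat) <- tax$leaf_order
    return(mat)
  }
  groups <- descendant_leaves(tax, level)
  idx <- lapply(groups, function(lv) match(lv, tax$leaf_order))
  out <- vapply(idx, function(j) rowSums(mat[, j, drop = FALSE]),
                numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, names(groups)))
  out
}

#' Roll leaf document counts up to a coarser level
#'
#' @param tax a [taxonomy()].
#' @param leaf_counts nonnegative integer vector over `leaf_order`.
#' @param level target level.
#' @return named integer vector of counts per level label; the grand total
#'   is preserved.
#' @export
roll_up_counts <- function(tax, leaf_counts, level) {
  level <- match.arg(level, TAXONOMY_LEVELS)
  if (length(leaf_counts) != length(tax$leaf_order)) {
    stop_littriage("leaf_counts length does not match taxonomy leaf_order",
                   "littriage_contract_error")
  }
  if (any(leaf_counts < 0) || any(leaf_counts != round(leaf_counts))) {
    stop_littriage("leaf_counts must be nonnegative integers",
                   "littriage_contract_error")
  }
  if (level == "sub-subclass") {
    return(stats::setNames(as.integer(leaf_counts), tax$leaf_order))
  }
  groups <- descendant_leaves(tax, level)
  vapply(groups, function(lv) {
    as.integer(sum(leaf_counts[match(lv, tax$leaf_order)]))
  }, integer(1))
}
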
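# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (explicit loops, closed forms) and never call the
# package code paths they are used to check.

toy_taxonomy <- function() {
  taxonomy(data.frame(
    id = c("orig", "nonorig", "sa", "sb", "sc",
           "a1", "a2", "b1", "c1", "c2"),
    name = c("ORIG", "NONORIG", "SA", "SB", "SC",
             "leaf a1", "leaf a2", "leaf b1", "leaf c1", "leaf c2"),
    level = c("class", "class", rep("subclass", 3), rep("sub-subclass", 5)),
    parent = c(NA, NA, "orig", "orig", "nonorig",
               "sa", "sa", "sb", "sc", "sc"),
    stringsAsFactors = FALSE
  ), name = "toy")
}

# one-hot probability matrix putting all mass on each document's leaf
onehot_matrix <- function(leaves, tax, doc_ids = NULL) {
  doc_ids <- doc_ids %||% sprintf("d%03d", seq_along(leaves))
  m <- matrix(0, length(leaves), length(tax$leaf_order))
  m[cbind(seq_along(leaves), match(leaves, tax$leaf_order))] <- 1
  prob_matrix(m, doc_ids, tax)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random valid leaf distributions (rows sum to 1)
random_prob_matrix <- function(n, tax, seed) {
  set.seed(seed)
  g <- matrix(stats::rgamma(n * length(tax$leaf_order), shape = 1),
              n, length(tax$leaf_order))
  prob_matrix(g / rowSums(g), sprintf("d%03d", seq_len(n)), tax)
}

# oracle: roll-up by explicit loop over leaves grouped by ancestor
oracle_rollup <- function(tax, p, level) {
  labs <- tax$nodes$id[tax$nodes$level == level]
  out <- stats::setNames(numeric(length(labs)), labs)
  for (i in seq_along(tax$leaf_order)) {
    lf <- tax$leaf_order[i]
    anc <- lf
    while (tax$nodes$level[tax$nodes$id == anc] != level) {
      anc <- tax$nodes$parent[tax$nodes$id == anc]
    }
    out[anc] <- out[anc] + p[i]
  }
  out
}

# oracle: voting decision from an explicit vote vector (labels, NA = abstain)
oracle_vote_decision <- function(cast, labs, rule, t, m_models) {
  cast <- cast[!is.na(cast)]
  v <- length(cast)
  thr <- switch(rule,
                threshold = t,
                majority = v %/% 2 + 1,
                unanimity = v)
  if (v == 0) return("UNKNOWN")
  tally <- sapply(labs, function(l) sum(cast == l))
  best <- max(tally)
  winners <- labs[tally == best]
  if (length(winners) == 1 && best >= thr) winners else "UNKNOWN"
}

# oracle: AUC as the Mann-Whitney U statistic with midrank tie handling
oracle_auc_u <- function(pos, score) {
  r <- rank(score)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# oracle: average precision at k for one document with a single relevant
# label, from the explicit P(i) * rel(i) sum
oracle_ap_at_k <- function(ranked_labels, true_label, k) {
  s <- 0
  for (i in seq_len(k)) {
    rel <- as.numeric(ranked_labels[i] == true_label)
    p_i <- sum(ranked_labels[seq_len(i)] == true_label) / i
    s <- s + p_i * rel
  }
  s / 1
}

# small labeled corpus with fully separable vocabulary, for classifier tests
tiny_corpus <- function(tax, n_per_leaf = 6, seed = 1) {
  set.seed(seed)
  leaves <- tax$leaf_order
  rows <- lapply(leaves, function(l) {
    sig <- gsub("[^a-z0-9]", "", l)
    tibble::tibble(
      doc_id = sprintf("%s_%02d", l, seq_len(n_per_leaf)),
      title = sprintf("study of %sword%d", sig, seq_len(n_per_leaf) %% 3),
      abstract = sprintf("we report %sword %stoken shared background text",
                         sig, sig),
      source = "PubMed",
      label = l
    )
  })
  do.call(rbind, rows)
}
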
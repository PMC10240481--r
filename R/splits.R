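#' Stratified k-fold train/dev/test assignment
#'
#' Builds `k` cross-validation folds whose test sets are disjoint and tile
#' the corpus. Within each fold the remaining documents are split into
#' train and dev at `train_frac`/`dev_frac` of the whole corpus (70%/10%
#' by default, with 20% test). Assignment is stratified by leaf label so
#' that rare sub-subclasses (down to ~0.5% prevalence in the default
#' collection) appear in every fold's test set whenever their counts
#' permit; leaves with fewer labeled documents than `k` trigger a warning
#' and are assigned without strict stratification.
#'
#' @param corpus a labeled corpus tibble.
#' @param k number of folds; `k * test_frac` must equal 1 so the test sets
#'   partition the corpus.
#' @param train_frac,dev_frac,test_frac role fractions, summing to 1.
#' @param seed integer seed; the same seed reproduces the same assignment.
#' @param stratify stratify by leaf label (default) or split label-blind.
#' @return a tibble with columns `fold` (0-based), `doc_id`, `role`
#'   (`train`/`dev`/`test`), with `k * nrow(corpus)` rows.
#' @export
kfold_split <- function(corpus, k = 5, train_frac = 0.7, dev_frac = 0.1,
                        test_frac = 0.2, seed = 1, stratify = TRUE) {
  if (abs(train_frac + dev_frac + test_frac - 1) > 1e-9) {
    stop_littriage("train/dev/test fractions must sum to 1",
                   "littriage_config_error")
  }
  if (abs(k * test_frac - 1) > 1e-9) {
    stop_littriage("k * test_frac must equal 1 (test sets tile the corpus)",
                   "littriage_config_error")
  }
  n <- nrow(corpus)
  if (n < k) {
    stop_littriage("corpus smaller than the number of folds",
                   "littriage_config_error")
  }
  strata <- if (stratify && "label" %in% names(corpus)) {
    s <- corpus$label
    s[is.na(s)] <- ".unlabeled"
    s
  } else rep("all", n)

  with_seed_local(seed, {
    small <- names(which(table(strata) < k))
    small <- setdiff(small, "all")
    if (length(small) > 0) {
      warning(sprintf(
        "leaf label(s) with fewer than k=%d documents; stratification relaxed: %s",
        k, paste(small, collapse = ", ")), call. = FALSE)
      strata[strata %in% small] <- ".small"
    }
    # test fold per document: every stratum spreads evenly over the k
    # folds, and per-stratum remainders go to the currently smallest folds
    # so the global test-set sizes tile the corpus as evenly as possible
    test_fold <- integer(n)
    fold_totals <- integer(k)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      folds_seq <- rep(seq_len(k) - 1L, m %/% k)
      r <- m %% k
      if (r > 0) {
        ord <- order(fold_totals + stats::runif(k) / 2) # random tie-break
        folds_seq <- c(folds_seq, ord[seq_len(r)] - 1L)
      }
      test_fold[idx] <- folds_seq
      fold_totals <- fold_totals + tabulate(folds_seq + 1L, k)
    }
    dev_share <- dev_frac / (train_frac + dev_frac)
    out <- vector("list", k)
    for (f in seq_len(k) - 1L) {
      role <- rep("train", n)
      role[test_fold == f] <- "test"
      rest <- which(test_fold != f)
      # stratified dev draw from the non-test 80%
      dev_idx <- integer(0)
      for (s in unique(strata[rest])) {
        pool <- rest[strata[rest] == s]
        n_dev <- round(length(pool) * dev_share)
        if (n_dev > 0) {
          dev_idx <- c(dev_idx, pool[sample.int(length(pool), n_dev)])
        }
      }
      role[dev_idx] <- "dev"
      out[[f + 1L]] <- tibble::tibble(fold = f, doc_id = corpus$doc_id,
                                      role = role)
    }
    do.call(rbind, out)
  })
}

#' Write or read a fold assignment file
#'
#' Delimited text with columns `doc_id`, `fold`, `role`.
#'
#' @param assignment tibble from [kfold_split()].
#' @param path file path.
#' @export
write_fold_assignment <- function(assignment, path) {
  utils::write.csv(assignment[, c("doc_id", "fold", "role")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_assignment
#' @export
read_fold_assignment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df[, c("fold", "doc_id", "role")])
}

# convenience: records of one fold in one role
fold_subset <- function(corpus, assignment, fold, role) {
  ids <- assignment$doc_id[assignment$fold == fold & assignment$role == role]
  corpus[match(ids, corpus$doc_id), , drop = FALSE]
}
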
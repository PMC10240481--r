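#' Read an annotated publication corpus
#'
#' A corpus is a tibble of publication records with columns `doc_id`,
#' `title`, `abstract`, `source` and an optional `label` column holding the
#' annotated sub-subclass id. JSONL carries one record per line (UTF-8);
#' CSV uses a header row with the same names and RFC-4180 quoting.
#'
#' @param path input file.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension when
#'   missing.
#' @param tax optional [taxonomy()]; when given, labels are checked to be
#'   leaves of it.
#' @return a tibble with one row per record, in file order.
#' @export
read_corpus <- function(path, format = NULL, tax = NULL) {
  if (!file.exists(path)) {
    stop_littriage(sprintf("file not found: %s", path), "littriage_io_error")
  }
  format <- format %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  format <- match.arg(format, c("jsonl", "csv"))
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
      if (is.null(rec)) {
        stop_littriage(sprintf("unparseable JSONL record at line %d", i),
                       "littriage_format_error")
      }
      recs[[i]] <- rec
    }
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(doc_id = as.character(r$doc_id %||% NA),
                 title = as.character(r$title %||% ""),
                 abstract = as.character(r$abstract %||% ""),
                 source = as.character(r$source %||% ""),
                 label = as.character(r$label %||% NA),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(doc_id = character(), title = character(),
                                      abstract = character(), source = character(),
                                      label = character(), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    req <- c("doc_id", "title", "abstract", "source")
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols) > 0) {
      stop_littriage(sprintf("corpus file missing column(s): %s",
                             paste(missing_cols, collapse = ", ")),
                     "littriage_format_error")
    }
    if (!"label" %in% names(df)) df$label <- NA_character_
    df <- df[, c("doc_id", "title", "abstract", "source", "label")]
    df$label[df$label == ""] <- NA_character_
  }
  validate_corpus(tibble::as_tibble(df), tax)
}

#' @rdname read_corpus
#' @param corpus a corpus tibble.
#' @export
write_corpus <- function(corpus, path, format = NULL) {
  format <- format %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  format <- match.arg(format, c("jsonl", "csv"))
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      r <- as.list(corpus[i, c("doc_id", "title", "abstract", "source", "label")])
      if (is.na(r$label)) r$label <- NULL
      writeLines(jsonlite::toJSON(r, auto_unbox = TRUE), con)
    }
  } else {
    utils::write.csv(corpus, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

validate_corpus <- function(corpus, tax = NULL) {
  if (anyNA(corpus$doc_id)) {
    stop_littriage("corpus has records without doc_id",
                   "littriage_validation_error")
  }
  dup <- unique(corpus$doc_id[duplicated(corpus$doc_id)])
  if (length(dup) > 0) {
    stop_littriage(sprintf("duplicate doc_id(s): %s",
                           paste(utils::head(dup, 5), collapse = ", ")),
                   "littriage_validation_error")
  }
  if (!is.null(tax) && "label" %in% names(corpus)) {
    lab <- corpus$label[!is.na(corpus$label)]
    bad <- setdiff(unique(lab), tax$leaf_order)
    if (length(bad) > 0) {
      stop_littriage(sprintf("label(s) not in taxonomy leaves: %s",
                             paste(utils::head(bad, 5), collapse = ", ")),
                     "littriage_validation_error")
    }
  }
  corpus
}

#' Drop records that cannot be classified
#'
#' Publications without a title or without an abstract are excluded from
#' training and evaluation; an absent source alone is not a reason for
#' exclusion.
#'
#' @param corpus a corpus tibble.
#' @return a list with `corpus` (retained records) and `excluded`
#'   (tibble of `doc_id`, `reason`).
#' @export
filter_incomplete <- function(corpus) {
  no_title <- is.na(corpus$title) | !nzchar(trimws(corpus$title))
  no_abstract <- is.na(corpus$abstract) | !nzchar(trimws(corpus$abstract))
  reason <- ifelse(no_title & no_abstract, "missing title and abstract",
            ifelse(no_title, "missing title",
            ifelse(no_abstract, "missing abstract", NA_character_)))
  keep <- is.na(reason)
  list(
    corpus = corpus[keep, , drop = FALSE],
    excluded = tibble::tibble(doc_id = corpus$doc_id[!keep],
                              reason = reason[!keep])
  )
}

#' Concatenate the classifier input text
#'
#' Title, abstract and source are joined in that order with single spaces,
#' after stripping leading/trailing whitespace; empty fields contribute
#' nothing. This is the exact text every classifier in the package sees.
#'
#' @param corpus a corpus tibble (or any data frame with `title`,
#'   `abstract`, `source`).
#' @return character vector, one input string per record.
#' @export
compose_input_text <- function(corpus) {
  vapply(seq_len(nrow(corpus)), function(i) {
    parts <- trimws(c(corpus$title[i], corpus$abstract[i], corpus$source[i]))
    parts[is.na(parts)] <- ""
    paste(parts[nzchar(parts)], collapse = " ")
  }, character(1))
}
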
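#' Tokenize classifier input text
#'
#' Lowercases and splits on any non-alphanumeric run, mirroring a plain
#' word-level bag-of-words view of the concatenated title + abstract +
#' source text.
#'
#' @param text character vector.
#' @return list of character vectors of tokens.
#' @export
tokenize_text <- function(text) {
  text <- tolower(text)
  toks <- strsplit(text, "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

# sparse documents x vocabulary count matrix
doc_term_matrix <- function(tokens, vocab) {
  i <- integer(0); j <- integer(0); x <- integer(0)
  for (d in seq_along(tokens)) {
    tb <- table(factor(tokens[[d]], levels = vocab))
    nz <- which(tb > 0)
    i <- c(i, rep.int(d, length(nz)))
    j <- c(j, nz)
    x <- c(x, as.integer(tb[nz]))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(tokens), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Fit the reference text classifier
#'
#' A multinomial logistic regression on token counts, standing behind the
#' same contract as any leaf-level probabilistic classifier: `fit` on a
#' labeled train/dev pair, then [predict_proba()] yielding a document x
#' sub-subclass probability matrix. The ridge penalty is chosen on the dev
#' set by micro F1 over a fixed grid, so the whole fit is deterministic
#' given the data.
#'
#' @param train labeled corpus tibble (every label a taxonomy leaf).
#' @param dev labeled corpus tibble used to select the penalty.
#' @param tax the active [taxonomy()].
#' @param config list with optional entries `nlambda` (number of penalty
#'   grid points, default 15), `lambda_min_ratio` (smallest penalty as a
#'   fraction of the largest, default 1e-3), `min_count` (minimum corpus
#'   frequency for a token to enter the vocabulary, default 2), and
#'   `model_name`.
#' @return an object of class `baseline_model`.
#' @details Leaves absent from the training set are flagged with a warning:
#'   the model can never predict them and their probability is reported as
#'   exactly zero. Degenerate sets with a single observed leaf yield a
#'   point-mass model on that leaf.
#' @export
fit_baseline <- function(train, dev, tax, config = list()) {
  if (nrow(train) == 0) {
    stop_littriage("empty training corpus", "littriage_validation_error")
  }
  validate_corpus(train, tax); validate_corpus(dev, tax)
  if (anyNA(train$label)) {
    stop_littriage("training corpus has unlabeled records",
                   "littriage_validation_error")
  }
  nlambda <- config$nlambda %||% 15
  lambda_min_ratio <- config$lambda_min_ratio %||% 1e-3
  min_count <- config$min_count %||% 2

  lab_counts <- table(factor(train$label, levels = tax$leaf_order))
  absent <- names(lab_counts)[lab_counts < 2]
  if (length(absent) > 0) {
    warning(sprintf(
      "leaf label(s) absent or singleton in training set (never predicted): %s",
      paste(absent, collapse = ", ")), call. = FALSE)
  }
  classes <- names(lab_counts)[lab_counts >= 2]
  if (length(classes) == 0) classes <- names(lab_counts)[lab_counts >= 1]
  train <- train[train$label %in% classes, , drop = FALSE]

  tokens <- tokenize_text(compose_input_text(train))
  counts <- table(unlist(tokens))
  vocab <- sort(names(counts[counts >= min_count]))
  if (length(vocab) == 0) {
    stop_littriage("empty vocabulary after frequency filtering",
                   "littriage_validation_error")
  }

  model <- list(vocab = vocab, classes = classes,
                taxonomy_fingerprint = tax$fingerprint,
                model_name = config$model_name %||% "baseline",
                class_prior = prop.table(table(factor(train$label,
                                                      levels = classes))))
  class(model) <- "baseline_model"

  if (length(classes) < 2) {
    model$kind <- "point_mass"
    return(model)
  }

  x <- doc_term_matrix(tokens, vocab)
  y <- factor(train$label, levels = classes)
  # ridge along glmnet's own decreasing path: the warm starts keep the
  # 22-class multinomial fit stable on unstandardized count features
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = FALSE)
  model$kind <- "glmnet"
  model$fit <- fit

  # penalty selection by dev micro F1 (equals accuracy for single-label data)
  dev_use <- dev[!is.na(dev$label), , drop = FALSE]
  if (nrow(dev_use) > 0 && length(fit$lambda) > 1) {
    xd <- doc_term_matrix(tokenize_text(compose_input_text(dev_use)), vocab)
    scores <- vapply(fit$lambda, function(l) {
      p <- multinom_response(fit, xd, l, classes)
      pred <- classes[apply(p, 1, which.max)]
      mean(pred == dev_use$label)
    }, numeric(1))
    model$lambda <- fit$lambda[which.max(scores)]
    model$dev_micro_f1 <- max(scores)
  } else {
    model$lambda <- min(fit$lambda)
  }
  model
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model '%s'> %d-token vocabulary, %d observed leaves",
              x$model_name, length(x$vocab), length(x$classes)))
  if (!is.null(x$lambda)) cat(sprintf(", lambda = %.4g", x$lambda))
  cat("\n")
  invisible(x)
}

#' Predict leaf probabilities for a corpus
#'
#' @param model a fitted `baseline_model`.
#' @param corpus corpus tibble (its text is re-composed internally).
#' @param tax the active [taxonomy()]; must match the taxonomy the model
#'   was fitted under.
#' @return a [prob_matrix()], rows in corpus order. Leaves unobserved in
#'   training get probability 0.
#' @export
predict_proba <- function(model, corpus, tax) {
  if (!identical(model$taxonomy_fingerprint, tax$fingerprint)) {
    stop_littriage("model was fitted under a different taxonomy",
                   "littriage_taxonomy_mismatch")
  }
  n <- nrow(corpus)
  if (n == 0) {
    return(prob_matrix(matrix(numeric(0), nrow = 0,
                              ncol = length(tax$leaf_order)),
                       character(0), tax))
  }
  if (model$kind == "point_mass") {
    p <- matrix(0, n, length(tax$leaf_order))
    p[, match(model$classes, tax$leaf_order)] <- 1
    return(prob_matrix(p, corpus$doc_id, tax))
  }
  x <- doc_term_matrix(tokenize_text(compose_input_text(corpus)), model$vocab)
  if (model$kind == "coefficients") {
    z <- as.matrix(x %*% model$W) +
      matrix(model$b, n, length(model$classes), byrow = TRUE)
    pr <- softmax_rows(z)
    colnames(pr) <- model$classes
  } else {
    pr <- multinom_response(model$fit, x, model$lambda, model$classes)
  }
  full <- matrix(0, n, length(tax$leaf_order),
                 dimnames = list(NULL, tax$leaf_order))
  full[, colnames(pr)] <- pr
  full <- full / rowSums(full)
  prob_matrix(full, corpus$doc_id, tax)
}

#' Persist and restore a fitted baseline model
#'
#' Plain-text JSON holding the vocabulary, per-class coefficients at the
#' selected penalty, class priors and the taxonomy fingerprint; loading
#' under a different taxonomy refuses to predict.
#'
#' @param model a `baseline_model`.
#' @param path file path.
#' @export
save_baseline <- function(model, path) {
  obj <- list(model_name = model$model_name, vocab = model$vocab,
              classes = model$classes, kind = model$kind,
              taxonomy_fingerprint = model$taxonomy_fingerprint,
              class_prior = as.numeric(model$class_prior),
              format_version = 1L)
  if (model$kind == "glmnet") {
    cf <- stats::coef(model$fit, s = model$lambda)
    obj$intercepts <- vapply(model$classes, function(cl) cf[[cl]][1, 1],
                             numeric(1))
    obj$coefficients <- lapply(model$classes, function(cl) {
      as.numeric(cf[[cl]][-1, 1])
    })
    names(obj$coefficients) <- model$classes
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_baseline
#' @return `load_baseline()` returns a `baseline_model` whose predictions
#'   are computed from the stored coefficients.
#' @export
load_baseline <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  model <- list(vocab = obj$vocab, classes = obj$classes,
                taxonomy_fingerprint = obj$taxonomy_fingerprint,
                model_name = obj$model_name, kind = obj$kind,
                class_prior = obj$class_prior)
  if (obj$kind == "glmnet") {
    model$kind <- "coefficients"
    model$W <- do.call(cbind, obj$coefficients[model$classes])
    model$b <- as.numeric(obj$intercepts) # stored in classes order
  }
  class(model) <- "baseline_model"
  model
}

# class probabilities via the overflow-safe softmax of the linear
# predictors (glmnet's own multinomial response can overflow to NaN on
# long documents)
multinom_response <- function(fit, x, lambda, classes) {
  z <- stats::predict(fit, x, s = lambda, type = "link")[, , 1]
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, classes))
  p <- softmax_rows(z)
  colnames(p) <- colnames(z)
  p
}

# dense coefficient view (vocab x classes weight matrix, intercept vector)
# used by prediction from persisted models and by attribution
baseline_coefficients <- function(model) {
  if (model$kind == "coefficients") {
    return(list(W = model$W, b = model$b))
  }
  if (model$kind != "glmnet") {
    stop_littriage("model has no linear coefficients", "littriage_lookup_error")
  }
  cf <- stats::coef(model$fit, s = model$lambda)
  W <- vapply(model$classes, function(cl) as.numeric(cf[[cl]][-1, 1]),
              numeric(length(model$vocab)))
  b <- vapply(model$classes, function(cl) cf[[cl]][1, 1], numeric(1))
  list(W = matrix(W, ncol = length(model$classes),
                  dimnames = list(model$vocab, model$classes)),
       b = as.numeric(b))
}

# linear scores + softmax for a coefficient-backed model
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
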
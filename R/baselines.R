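# Comparison systems: a weighted random classifier and a linear-kernel
# SVM over tf-idf n-gram (up to trigram) features.

#' Weighted random predictions
#'
#' Predicts each test item positive independently with probability equal
#' to the training-set positive prevalence.  Expected positive-class
#' precision, recall and F1 all equal that prevalence.
#'
#' @param labels_train training labels (0/1, both classes present).
#' @param n_test number of predictions to draw.
#' @param seed RNG seed.
#' @return integer vector of 0/1 predictions.
#' @export
random_weighted_predict <- function(labels_train, n_test, seed = 1L) {
  q <- mean(labels_train == 1L)
  n_test <- stopifnot_scalar_int(n_test, "n_test")
  with_seed(seed, as.integer(stats::runif(n_test) < q))
}

#' Fit the weighted random baseline
#'
#' @param tokens a labeled \code{tokenized_corpus} (or an integer label
#'   vector).
#' @return object of class \code{random_model} storing the training
#'   prevalence.
#' @export
random_baseline <- function(tokens) {
  y <- if (inherits(tokens, "tokenized_corpus")) tokens$label else tokens
  if (anyNA(y)) stop("labels must be complete", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes", call. = FALSE)
  structure(list(prevalence = mean(y == 1L), n_train = length(y)),
            class = c("random_model", "ade_model"))
}

#' @exportS3Method base::print
print.random_model <- function(x, ...) {
  cat(sprintf("Weighted random baseline: P(positive) = %.4f (from %d labels)\n",
              x$prevalence, x$n_train))
  invisible(x)
}

#' Predict from the weighted random baseline
#'
#' @param object a \code{random_model}.
#' @param tokens a \code{tokenized_corpus}, or a single integer giving the
#'   number of predictions.
#' @param type \code{"class"} or \code{"prob"} (the constant prevalence).
#' @param seed RNG seed for the draw.
#' @param ... unused.
#' @export
predict.random_model <- function(object, tokens, type = c("class", "prob"),
                                 seed = 1L, ...) {
  type <- match.arg(type)
  n <- if (inherits(tokens, "tokenized_corpus")) length(tokens$tokens)
       else stopifnot_scalar_int(tokens, "tokens")
  if (type == "prob") return(rep(object$prevalence, n))
  with_seed(seed, as.integer(stats::runif(n) < object$prevalence))
}

## ---- tf-idf featurizer ------------------------------------------------

token_ngrams <- function(tokens, n_max = 3L, type = "word") {
  if (type == "char") {
    chars <- strsplit(paste(tokens, collapse = " "), "")[[1L]]
    tokens <- chars
  }
  n <- length(tokens)
  out <- tokens
  if (n_max >= 2L && n >= 2L)
    out <- c(out, paste(tokens[-n], tokens[-1L], sep = "_"))
  if (n_max >= 3L && n >= 3L)
    out <- c(out, paste(tokens[1:(n - 2L)], tokens[2:(n - 1L)],
                        tokens[3:n], sep = "_"))
  out
}

# Sparse term-count matrix over a fixed vocabulary.
ngram_counts <- function(tok_list, vocab, n_max, type) {
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(tok_list)) {
    gr <- token_ngrams(tok_list[[d]], n_max, type)
    idx <- match(gr, vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    cnt <- table(idx)
    ii <- c(ii, rep(d, length(cnt)))
    jj <- c(jj, as.integer(names(cnt)))
    xx <- c(xx, as.integer(cnt))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                       dims = c(length(tok_list), length(vocab)))
}

# tf-idf with smoothed idf and L2-normalized rows.
tfidf_transform <- function(counts, idf) {
  X <- counts %*% Matrix::Diagonal(x = idf)
  nrm <- sqrt(Matrix::rowSums(X^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% X
}

#' Fit the SVM baseline over tf-idf n-gram features
#'
#' Word n-grams up to trigrams (character mode behind \code{ngram_type}),
#' tf-idf weighting with smoothed idf and L2-normalized rows, and a
#' linear-kernel SVM with library-default hyperparameters.  The fit is
#' deterministic given the data.
#'
#' @param tokens labeled \code{tokenized_corpus} (both classes present).
#' @param ngram_max longest n-gram (default 3).
#' @param ngram_type \code{"word"} (default) or \code{"char"}.
#' @return object of class \code{svm_model} wrapping the fitted SVM plus
#'   the training vocabulary and idf weights.
#' @export
svm_tfidf <- function(tokens, ngram_max = 3L, ngram_type = c("word", "char")) {
  stopifnot(inherits(tokens, "tokenized_corpus"))
  ngram_type <- match.arg(ngram_type)
  y <- tokens$label
  if (anyNA(y)) stop("labels must be complete", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training corpus must contain both classes", call. = FALSE)
  grams <- lapply(tokens$tokens, token_ngrams, n_max = ngram_max,
                  type = ngram_type)
  vocab <- sort(unique(unlist(grams, use.names = FALSE)), method = "radix")
  counts <- ngram_counts(tokens$tokens, vocab, ngram_max, ngram_type)
  df <- Matrix::colSums(counts > 0)
  idf <- log((1 + nrow(counts)) / (1 + df)) + 1
  X <- tfidf_transform(counts, idf)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                    kernel = "linear", scale = FALSE)
  structure(list(fit = fit, vocab = vocab, idf = idf,
                 ngram_max = ngram_max, ngram_type = ngram_type,
                 n_train = length(y)),
            class = c("svm_model", "ade_model"))
}

#' @exportS3Method base::print
print.svm_model <- function(x, ...) {
  cat(sprintf("Linear SVM over tf-idf %s n-grams (max n = %d): %d features, %d support vectors\n",
              x$ngram_type, x$ngram_max, length(x$vocab),
              x$fit$tot.nSV))
  invisible(x)
}

#' Predict from the SVM baseline
#'
#' @param object an \code{svm_model}.
#' @param tokens a \code{tokenized_corpus}.
#' @param type \code{"class"} (0/1) or \code{"decision"} (signed linear
#'   score for the positive class).
#' @param ... unused.
#' @export
predict.svm_model <- function(object, tokens,
                              type = c("class", "decision"), ...) {
  type <- match.arg(type)
  counts <- ngram_counts(tokens$tokens, object$vocab, object$ngram_max,
                         object$ngram_type)
  X <- tfidf_transform(counts, object$idf)
  if (type == "class")
    return(as.integer(as.character(predict(object$fit, X))))
  dv <- attr(predict(object$fit, X, decision.values = TRUE),
             "decision.values")
  # orient so positive score means positive class
  d <- dv[, 1L]
  if (grepl("^0/", colnames(dv)[1L])) d <- -d
  unname(d)
}
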
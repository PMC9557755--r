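# Evaluation: positive-class precision/recall/F1, the multi-run mean+-SD
# protocol, best-run selection, train/validation splitting and the
# drug-filter -> classifier screening pipeline.

#' Positive-class precision, recall and F1
#'
#' All three metrics are for the positive (ADE) class.  Zero denominators
#' (no predicted positives, or no gold positives) yield 0 with a warning.
#'
#' @param gold,pred equal-length 0/1 label vectors.
#' @return object of class \code{eval_metrics}: list with
#'   \code{precision}, \code{recall}, \code{f1} and the confusion counts
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @examples
#' compute_metrics(c(1,1,1,0,0,1,1,0), c(1,1,1,1,0,0,0,0))
#' @export
compute_metrics <- function(gold, pred) {
  if (length(gold) != length(pred))
    stop("'gold' and 'pred' must have equal length", call. = FALSE)
  gold <- as.integer(gold); pred <- as.integer(pred)
  tp <- sum(gold == 1L & pred == 1L)
  fp <- sum(gold == 0L & pred == 1L)
  fn <- sum(gold == 1L & pred == 0L)
  tn <- sum(gold == 0L & pred == 0L)
  if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0", call. = FALSE)
    precision <- 0
  } else precision <- tp / (tp + fp)
  if (tp + fn == 0L) {
    warning("no gold positives; recall reported as 0", call. = FALSE)
    recall <- 0
  } else recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall /
          (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "eval_metrics")
}

#' @exportS3Method base::print
print.eval_metrics <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (TP %d, FP %d, FN %d, TN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# Population standard deviation (divisor n), matching a report over a
# fixed set of runs rather than a sample estimate.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Multi-run evaluation protocol
#'
#' Runs \code{run_fun} once per seed (\code{base_seed}, \code{base_seed +
#' 1}, ...), collecting positive-class metrics, and reports their mean and
#' population SD; per-run values are retained for best-run selection.
#'
#' @param run_fun function of one argument (the seed) returning an
#'   \code{eval_metrics} or any list with \code{precision}, \code{recall},
#'   \code{f1}.
#' @param n_runs number of runs (default 10).
#' @param base_seed seed of the first run (default 1).
#' @return object of class \code{eval_report}: list with \code{runs}
#'   (data frame seed/precision/recall/f1), \code{mean}, \code{sd} and
#'   \code{n_runs}.
#' @export
multi_run <- function(run_fun, n_runs = 10L, base_seed = 1L) {
  n_runs <- stopifnot_scalar_int(n_runs, "n_runs")
  seeds <- base_seed + seq_len(n_runs) - 1L
  rows <- lapply(seeds, function(s) {
    m <- run_fun(s)
    data.frame(seed = s, precision = m$precision, recall = m$recall,
               f1 = m$f1)
  })
  runs <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "f1")
  structure(list(runs = runs,
                 mean = vapply(runs[metric_cols], mean, 0),
                 sd = vapply(runs[metric_cols], pop_sd, 0),
                 n_runs = n_runs),
            class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, digits = 3L, ...) {
  fmt <- function(m, s) sprintf("%.*f (%.*g)", digits, m, 2L, s)
  cat(sprintf("Average performance of %d runs\n", x$n_runs))
  cat(sprintf("  Precision %s  Recall %s  F1 %s\n",
              fmt(x$mean["precision"], x$sd["precision"]),
              fmt(x$mean["recall"], x$sd["recall"]),
              fmt(x$mean["f1"], x$sd["f1"])))
  invisible(x)
}

#' Select the best run of an evaluation report
#'
#' The run with maximal validation F1; ties go to the earliest (lowest)
#' seed.
#'
#' @param report an \code{eval_report}.
#' @return the row index of the best run (its seed is
#'   \code{report$runs$seed[i]}).
#' @export
select_best <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  which.max(report$runs$f1)
}

#' Format evaluation reports as a results table
#'
#' One row per model, columns \code{model}, \code{precision},
#' \code{recall}, \code{f1}, each metric printed as "mean (SD)".
#'
#' @param reports named list of \code{eval_report} objects.
#' @param digits digits for the means.
#' @return data frame of formatted strings.
#' @export
format_eval_table <- function(reports, digits = 3L) {
  fmt <- function(m, s) sprintf("%.*f (%.*g)", digits, m, 2L, s)
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm,
               precision = fmt(r$mean["precision"], r$sd["precision"]),
               recall = fmt(r$mean["recall"], r$sd["recall"]),
               f1 = fmt(r$mean["f1"], r$sd["f1"]),
               stringsAsFactors = FALSE)
  }))
}

#' Seeded train/validation split
#'
#' Random, seeded, by default stratified by label so both splits keep the
#' corpus prevalence.  The training share defaults to 0.814 (the
#' 81.4\%/18.6\% protocol); the training count is exactly
#' \code{round(n * train_frac)}.
#'
#' @param tokens a \code{tokenized_corpus}.
#' @param train_frac training fraction (default 0.814).
#' @param seed RNG seed.
#' @param stratify stratify by label (default \code{TRUE}; tweets with
#'   missing labels cannot be stratified).
#' @return list with \code{train} and \code{valid}
#'   (\code{tokenized_corpus} objects).
#' @export
split_corpus <- function(tokens, train_frac = 0.814, seed = 1L,
                         stratify = TRUE) {
  stopifnot(inherits(tokens, "tokenized_corpus"))
  train_frac <- stopifnot_prob(train_frac, "train_frac")
  n <- length(tokens$tokens)
  n_train <- round(n * train_frac)
  if (stratify && !anyNA(tokens$label)) {
    idx_by_class <- split(seq_len(n), tokens$label)
    # per-class counts by largest remainder so the total is exact
    exact <- vapply(idx_by_class, length, 0L) * train_frac
    base <- floor(exact)
    rem <- n_train - sum(base)
    ord <- order(-(exact - base))
    take <- base
    if (rem > 0) take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
    train_idx <- with_seed(seed, unlist(lapply(seq_along(idx_by_class),
      function(k) sample(idx_by_class[[k]], take[k])), use.names = FALSE))
  } else {
    train_idx <- with_seed(seed, sample.int(n, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = tokens[train_idx], valid = tokens[-train_idx])
}

#' Screen a raw corpus for ADE tweets
#'
#' The two-stage pipeline: keep tweets with at least one drug-lexicon
#' mention, then apply a trained classifier to the survivors.  The stage
#' counts are nested: predicted-ADE tweets are a subset of drug-mentioning
#' tweets, which are a subset of the corpus.
#'
#' @param corpus data frame of raw tweets.
#' @param lexicon a \code{drug_lexicon}.
#' @param model any fitted classifier with a \code{predict(model, tokens,
#'   type = "class")} method (\code{clapa_model}, \code{encoder_model},
#'   \code{baclapa_model}, \code{svm_model}, \code{rule_model}, ...).
#' @param ... passed to \code{predict} (e.g. \code{seed}).
#' @return object of class \code{screen_report}: list with \code{n_total},
#'   \code{n_drug}, \code{n_ade} and \code{ade_ids} (tweet ids predicted
#'   positive).
#' @export
screen_corpus <- function(corpus, lexicon, model, ...) {
  n_total <- nrow(corpus)
  drug_tok <- filter_corpus_by_drugs(corpus, lexicon)
  n_drug <- length(drug_tok$tokens)
  if (n_drug == 0L) {
    return(structure(list(n_total = n_total, n_drug = 0L, n_ade = 0L,
                          ade_ids = character(0)),
                     class = "screen_report"))
  }
  pred <- predict(model, drug_tok, type = "class", ...)
  structure(list(n_total = n_total, n_drug = n_drug,
                 n_ade = sum(pred == 1L),
                 ade_ids = drug_tok$tweet_id[pred == 1L]),
            class = "screen_report")
}

#' @exportS3Method base::print
print.screen_report <- function(x, ...) {
  cat(sprintf("Screening: %d tweets -> %d drug-mentioning -> %d predicted ADE\n",
              x$n_total, x$n_drug, x$n_ade))
  invisible(x)
}

#' Rule-based reference classifier
#'
#' Predicts positive when the tweet contains any of the given
#' adverse-event phrases as a contiguous (normalized) token subsequence.
#' On noise-free synthetic corpora, whose positives are exactly the
#' drug-plus-phrase tweets, this rule is a perfect reference.
#'
#' @param ade_phrases character vector of phrases.
#' @return object of class \code{rule_model}.
#' @export
rule_classifier <- function(ade_phrases) {
  phr <- lapply(ade_phrases, function(p)
    strsplit(tolower(trimws(p)), "\\s+")[[1L]])
  structure(list(phrases = phr), class = c("rule_model", "ade_model"))
}

#' @exportS3Method base::print
print.rule_model <- function(x, ...) {
  cat(sprintf("Rule-based classifier: positive iff any of %d phrases present\n",
              length(x$phrases)))
  invisible(x)
}

has_subseq <- function(tokens, phrase) {
  np <- length(phrase); nt <- length(tokens)
  if (np > nt) return(FALSE)
  for (i in seq_len(nt - np + 1L))
    if (all(tokens[i:(i + np - 1L)] == phrase)) return(TRUE)
  FALSE
}

#' Predict from the rule-based classifier
#'
#' @param object a \code{rule_model}.
#' @param tokens a \code{tokenized_corpus}.
#' @param type only \code{"class"}.
#' @param ... unused.
#' @export
predict.rule_model <- function(object, tokens, type = "class", ...) {
  vapply(tokens$tokens, function(tk)
    as.integer(any(vapply(object$phrases, function(p) has_subseq(tk, p),
                          logical(1)))), 0L)
}
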
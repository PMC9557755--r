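# Corpus, lexicon and word-vector file formats.
#
# The corpus dialect is the shared-task style: UTF-8 tab-separated values
# with a header row and columns tweet_id, text and (optionally) label.

#' Read a tweet corpus from a tab-separated file
#'
#' The file must carry a header row with columns \code{tweet_id} and
#' \code{text}; a binary \code{label} column (1 = ADE, 0 = non-ADE) is
#' optional.  Labels may be missing (\code{NA}) for unlabeled tweets, e.g.
#' screening-stage corpora.
#'
#' @param path path to a TSV file.
#' @return a data frame with columns \code{tweet_id} (character),
#'   \code{text} (character) and \code{label} (integer, possibly \code{NA}).
#' @export
read_corpus <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("tweet_id", "text") %in% names(df)))
    stop("corpus file must have 'tweet_id' and 'text' columns", call. = FALSE)
  lab <- if ("label" %in% names(df)) {
    suppressWarnings(as.integer(df$label))
  } else rep(NA_integer_, nrow(df))
  bad <- !is.na(lab) & !(lab %in% c(0L, 1L))
  if (any(bad))
    stop("labels must be 0 or 1; offending tweet_id: ",
         df$tweet_id[which(bad)[1L]], call. = FALSE)
  data.frame(tweet_id = df$tweet_id, text = df$text, label = lab,
             stringsAsFactors = FALSE)
}

#' Write a tweet corpus to a tab-separated file
#'
#' @param corpus data frame with \code{tweet_id}, \code{text} and optionally
#'   \code{label}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  cols <- intersect(c("tweet_id", "text", "label"), names(corpus))
  utils::write.table(corpus[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a drug-name list
#'
#' Plain text, one name per line; blank lines and lines starting with
#' \code{#} are skipped.  Names are not yet case-folded or de-duplicated;
#' pass the result to \code{\link{build_lexicon}}.
#'
#' @param path path to the name list.
#' @return character vector of raw names.
#' @export
read_name_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a drug lexicon to a plain-text name list
#'
#' @param lexicon a \code{drug_lexicon}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  writeLines(lexicon$names, path, useBytes = TRUE)
  invisible(path)
}

#' Read word vectors in the word2vec/fastText text format
#'
#' First line is \code{"<count> <dim>"}; each following line is a word and
#' \code{dim} numbers, space separated.
#'
#' @param path path to the vector file.
#' @return an \code{embedding_table} (see \code{\link{embedding_table}}).
#' @export
read_word_vectors <- function(path) {
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- scan(con, what = numeric(), n = 2, quiet = TRUE)
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  words <- character(n)
  mat <- matrix(0, n, d)
  for (i in seq_len(n)) {
    words[i] <- scan(con, what = character(), n = 1, quiet = TRUE)
    mat[i, ] <- scan(con, what = numeric(), n = d, quiet = TRUE)
  }
  rownames(mat) <- words
  embedding_table(mat)
}

#' Write word vectors in the word2vec/fastText text format
#'
#' @param table an \code{embedding_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_word_vectors <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  m <- table$vectors
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(rownames(m)[i], paste(formatC(m[i, ], format = "g", digits = 8),
                                collapse = " ")), "")
  writeLines(body, con)
  invisible(path)
}
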
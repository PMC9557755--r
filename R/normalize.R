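# Tweet normalization: URLs out, user mentions and emoticons to placeholder
# tokens, special characters stripped, punctuation separated, lowercased.

USER_TOKEN <- "<user>"
EMOTICON_TOKEN <- "<emoticon>"

#' Default emoticon table
#'
#' The emoticon-to-placeholder table shipped with the package
#' (\code{inst/extdata/emoticons.txt}): one emoticon per line, lines
#' starting with \code{"# "} being comments.  Matching is against whole
#' whitespace-delimited tokens.
#'
#' @return character vector of emoticon strings.
#' @export
default_emoticons <- function() {
  path <- system.file("extdata", "emoticons.txt", package = "adetect",
                      mustWork = TRUE)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- x[nzchar(x) & !startsWith(x, "# ")]
  x
}

#' Normalize a raw tweet into a token sequence
#'
#' Applies, in order: removal of URL-shaped substrings; replacement of
#' whitespace-delimited tokens beginning with \code{@} by \code{<user>};
#' replacement of tokens found in the emoticon table by \code{<emoticon>};
#' removal of special characters (non-ASCII and control characters);
#' separation of punctuation marks into standalone tokens; lowercasing.
#' The placeholder tokens themselves are never re-split.
#'
#' A tweet that normalizes to nothing (e.g. a bare URL) yields a
#' zero-length vector; callers decide whether to drop or keep such tweets.
#'
#' @param text a single raw tweet string.
#' @param emoticons character vector of emoticon strings
#'   (default \code{\link{default_emoticons}()}).
#' @return character vector of lowercase tokens (possibly empty).
#' @examples
#' normalize_tweet("@john Advil gave me a headache :( http://t.co/abc")
#' normalize_tweet("took 2 ADVIL!!")
#' @export
normalize_tweet <- function(text, emoticons = default_emoticons()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("tweet text is empty", call. = FALSE)
  text <- gsub("(https?://\\S+|www\\.\\S+)", " ", text, perl = TRUE)
  raw_toks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1L]]
  if (length(raw_toks) == 0L) return(character(0))
  out <- lapply(raw_toks, function(tok) {
    if (tok %in% c(USER_TOKEN, EMOTICON_TOKEN)) return(tok)
    if (startsWith(tok, "@") && nchar(tok) > 1L) return(USER_TOKEN)
    if (tok %in% emoticons) return(EMOTICON_TOKEN)
    # special characters: keep printable ASCII only
    tok <- gsub("[^\x20-\x7e]", "", tok, perl = TRUE)
    # punctuation marks become standalone tokens
    tok <- gsub("([[:punct:]])", " \\1 ", tok, perl = TRUE)
    toks <- strsplit(trimws(tok), "\\s+", perl = TRUE)[[1L]]
    tolower(toks)
  })
  toks <- unlist(out, use.names = FALSE)
  toks[nzchar(toks)]
}

#' Normalize a corpus of raw tweets
#'
#' @param corpus data frame as returned by \code{\link{read_corpus}}.
#' @param emoticons emoticon table (see \code{\link{normalize_tweet}}).
#' @param drop_empty drop tweets whose normalization is empty
#'   (default \code{TRUE}); if kept they carry zero-length token vectors.
#' @return a \code{tokenized_corpus}: list with components \code{tweet_id},
#'   \code{tokens} (list of character vectors) and \code{label}.
#' @export
normalize_corpus <- function(corpus, emoticons = default_emoticons(),
                             drop_empty = TRUE) {
  stopifnot(is.data.frame(corpus), all(c("tweet_id", "text") %in% names(corpus)))
  toks <- lapply(corpus$text, normalize_tweet, emoticons = emoticons)
  lab <- if ("label" %in% names(corpus)) as.integer(corpus$label)
         else rep(NA_integer_, nrow(corpus))
  keep <- if (drop_empty) lengths(toks) > 0L else rep(TRUE, length(toks))
  structure(list(tweet_id = corpus$tweet_id[keep],
                 tokens   = toks[keep],
                 label    = lab[keep]),
            class = "tokenized_corpus")
}

#' @exportS3Method base::print
print.tokenized_corpus <- function(x, ...) {
  n <- length(x$tokens)
  nlab <- sum(!is.na(x$label))
  cat(sprintf("Tokenized corpus: %d tweets (%d labeled, %d positive)\n",
              n, nlab, sum(x$label == 1L, na.rm = TRUE)))
  if (n > 0)
    cat(" e.g.:", paste(utils::head(x$tokens[[1L]], 12L), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.tokenized_corpus` <- function(x, i) {
  structure(list(tweet_id = x$tweet_id[i], tokens = x$tokens[i],
                 label = x$label[i]), class = "tokenized_corpus")
}

#' @export
length.tokenized_corpus <- function(x) length(x$tokens)

#' Write a tokenized corpus as TSV
#'
#' Columns \code{tweet_id}, \code{tokens} (space-joined) and \code{label}.
#'
#' @param tokens a \code{tokenized_corpus}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tokens <- function(tokens, path) {
  stopifnot(inherits(tokens, "tokenized_corpus"))
  df <- data.frame(tweet_id = tokens$tweet_id,
                   tokens = vapply(tokens$tokens, paste, "", collapse = " "),
                   label = tokens$label, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tokenized corpus written by \code{write_tokens}
#'
#' @param path path to the TSV file.
#' @return a \code{tokenized_corpus}.
#' @export
read_tokens <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  structure(list(tweet_id = df$tweet_id,
                 tokens = strsplit(df$tokens, " ", fixed = TRUE),
                 label = suppressWarnings(as.integer(df$label))),
            class = "tokenized_corpus")
}
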
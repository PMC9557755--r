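# Drug-name lexicon: the medical-concept set used for mention matching,
# corpus screening and collocation-graph pruning.

#' Build a drug lexicon
#'
#' Combines a base name list (e.g. generic and brand names from a drug
#' reference) with corpus-supplied additions, removing a stoplist of
#' generic words that collide with everyday language (e.g. "amen",
#' "heather").  All lookups are case-insensitive: names are folded to
#' lower case and de-duplicated; the provenance of each retained name
#' (\code{"base"} or \code{"corpus"}) is recorded.
#'
#' @param base_names character vector of base drug names (non-empty).
#' @param stoplist character vector of names to exclude (default none).
#' @param additions character vector of corpus-derived names to add
#'   (default none).
#' @return an object of class \code{drug_lexicon}: list with \code{names}
#'   (sorted lowercase character vector) and \code{source} (parallel
#'   character vector, \code{"base"} or \code{"corpus"}).
#' @examples
#' lex <- build_lexicon(c("Advil", "Amen"), stoplist = "amen",
#'                      additions = "tylenol")
#' lex$names
#' @export
build_lexicon <- function(base_names, stoplist = character(),
                          additions = character()) {
  if (length(base_names) == 0L)
    stop("'base_names' must be non-empty", call. = FALSE)
  norm <- function(x) unique(tolower(trimws(x)))
  base <- setdiff(norm(base_names), norm(stoplist))
  add  <- setdiff(setdiff(norm(additions), norm(stoplist)), base)
  names_all <- c(base, add)
  src <- c(rep("base", length(base)), rep("corpus", length(add)))
  ord <- order(names_all, method = "radix")
  structure(list(names = names_all[ord], source = src[ord]),
            class = "drug_lexicon")
}

#' @exportS3Method base::print
print.drug_lexicon <- function(x, ...) {
  cat(sprintf("Drug lexicon: %d names (%d base, %d corpus-added)\n",
              length(x$names), sum(x$source == "base"),
              sum(x$source == "corpus")))
  invisible(x)
}

#' @export
length.drug_lexicon <- function(x) length(x$names)

# Max words across lexicon names; bounds the n-gram length scanned by the
# longest-match-first matcher.
lexicon_max_words <- function(lex) {
  if (length(lex$names) == 0L) return(1L)
  max(lengths(strsplit(lex$names, " ", fixed = TRUE)))
}

#' Find drug mentions in a tokenized tweet
#'
#' Scans the token sequence left to right, longest match first, against
#' the lexicon; multi-word names match a space-joined token n-gram.
#' Matching is exact after case folding: typos (e.g. "vioxe" for "vioxx")
#' do not match.
#'
#' @param tokens character vector of normalized tokens.
#' @param lexicon a \code{drug_lexicon}.
#' @return data frame with one row per mention: \code{start}, \code{end}
#'   (token indices, inclusive) and \code{name} (the matched lexicon
#'   name); zero rows when no mention.
#' @export
find_drug_mentions <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  n <- length(tokens)
  maxw <- min(lexicon_max_words(lexicon), n)
  starts <- integer(0); ends <- integer(0); names_hit <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (w in seq.int(min(maxw, n - i + 1L), 1L)) {
      cand <- paste(tokens[i:(i + w - 1L)], collapse = " ")
      if (cand %in% lexicon$names) { hit <- w; break }
    }
    if (hit > 0L) {
      starts <- c(starts, i); ends <- c(ends, i + hit - 1L)
      names_hit <- c(names_hit, paste(tokens[i:(i + hit - 1L)], collapse = " "))
      i <- i + hit
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends, name = names_hit,
             stringsAsFactors = FALSE)
}

#' Filter a raw corpus to drug-mentioning tweets
#'
#' Normalizes every tweet and retains exactly those with at least one
#' lexicon mention — the first stage of the ADE screening pipeline.
#'
#' @param corpus data frame of raw tweets (\code{tweet_id}, \code{text},
#'   optional \code{label}).
#' @param lexicon a \code{drug_lexicon}.
#' @param emoticons emoticon table passed to \code{\link{normalize_tweet}}.
#' @return a \code{tokenized_corpus} containing only drug-mentioning
#'   tweets, in input order.
#' @export
filter_corpus_by_drugs <- function(corpus, lexicon,
                                   emoticons = default_emoticons()) {
  tok <- normalize_corpus(corpus, emoticons = emoticons, drop_empty = TRUE)
  has_drug <- vapply(tok$tokens, function(t)
    nrow(find_drug_mentions(t, lexicon)) > 0L, logical(1))
  tok[has_drug]
}
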
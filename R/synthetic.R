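# Seeded synthetic tweet corpora with planted ADE structure, so every
# pipeline stage is testable without any external data.  Positives contain
# a drug name co-occurring with an adverse-event phrase, labeled negatives
# contain a drug name with a benign phrase, distractors contain no drug at
# all (they exercise the screening filter and carry no label).

default_drug_vocab <- function() c(
  "advil", "tylenol", "benadryl", "ibuprofen", "xanax", "ambien",
  "zoloft", "prozac", "adderall", "melatonin", "aspirin", "nyquil",
  "claritin", "metformin", "lipitor", "codeine", "tramadol", "naproxen",
  "vitamin d", "fish oil")

default_ade_phrases <- function() c(
  "gave me a headache", "made me so dizzy", "could not sleep at all",
  "feeling sick to my stomach", "made me break out in hives",
  "knocked me out cold", "made me gain weight",
  "gave me the worst nausea", "made my heart race",
  "left me completely exhausted", "made me itch everywhere",
  "gave me awful stomach cramps")

default_benign_phrases <- function() c(
  "worked like a charm", "cleared everything right up",
  "no problems at all", "best thing ever", "did absolutely nothing",
  "finally kicked in", "got it on sale", "doctor said keep taking it",
  "totally recommend it", "same dose as always")

default_fillers <- function() c(
  "i", "my", "the", "so", "just", "today", "again", "this", "morning",
  "night", "really", "after", "work", "been", "taking", "took", "some",
  "and", "then", "still", "feel", "but", "ok", "well", "honestly", "lol")

#' Specification of a synthetic tweet corpus
#'
#' The generator's statistical frame mirrors the training data it stands
#' in for: short noisy texts, roughly 9.6\% ADE prevalence among
#' drug-mentioning tweets (2362/24700), every positive containing at least
#' one drug token together with an adverse-event phrase, every labeled
#' negative a drug token without one, plus optional drug-free distractor
#' tweets for screening tests.
#'
#' @param n_tweets total tweets (labeled + distractors).
#' @param ade_prevalence positive share among labeled (drug-bearing)
#'   tweets; default \code{2362/24700}.  The positive count is exact:
#'   \code{round(n_labeled * ade_prevalence)}.
#' @param drug_vocab drug-name strings (may contain multi-word names).
#' @param ade_phrases adverse-event phrases planted in positives.
#' @param benign_phrases phrases planted in negatives.
#' @param fillers background vocabulary.
#' @param distractor_fraction share of drug-free distractor tweets
#'   (default 0); their count is \code{round(n_tweets *
#'   distractor_fraction)} and they carry label \code{NA}.
#' @param noise list of rates in [0, 1]: \code{typo} (corrupt the drug
#'   surface form), \code{emoticon}, \code{url}, \code{mention}
#'   (inject the respective token), \code{phrase_dropout} (drop a
#'   positive's ADE phrase while keeping its label — label noise).
#'   All default 0.
#' @param seed RNG seed; the same spec and seed regenerate the corpus
#'   bit for bit.
#' @return object of class \code{corpus_spec}.
#' @export
corpus_spec <- function(n_tweets = 1000L, ade_prevalence = 2362 / 24700,
                        drug_vocab = default_drug_vocab(),
                        ade_phrases = default_ade_phrases(),
                        benign_phrases = default_benign_phrases(),
                        fillers = default_fillers(),
                        distractor_fraction = 0,
                        noise = list(), seed = 1L) {
  noise_def <- list(typo = 0, emoticon = 0, url = 0, mention = 0,
                    phrase_dropout = 0)
  bad <- setdiff(names(noise), names(noise_def))
  if (length(bad))
    stop("unknown noise field: ", bad[1L], call. = FALSE)
  noise_def[names(noise)] <- noise
  for (nm in names(noise_def)) stopifnot_prob(noise_def[[nm]], nm)
  if (length(drug_vocab) == 0L)
    stop("'drug_vocab' must be non-empty", call. = FALSE)
  if (length(ade_phrases) == 0L)
    stop("'ade_phrases' must be non-empty", call. = FALSE)
  structure(list(
    n_tweets = stopifnot_scalar_int(n_tweets, "n_tweets"),
    ade_prevalence = stopifnot_prob(ade_prevalence, "ade_prevalence"),
    drug_vocab = tolower(drug_vocab),
    ade_phrases = tolower(ade_phrases),
    benign_phrases = tolower(benign_phrases),
    fillers = tolower(fillers),
    distractor_fraction = stopifnot_prob(distractor_fraction,
                                         "distractor_fraction"),
    noise = noise_def,
    seed = stopifnot_scalar_int(seed, "seed", min = 0L)),
    class = "corpus_spec")
}

#' @exportS3Method base::print
print.corpus_spec <- function(x, ...) {
  cat(sprintf("Corpus spec: %d tweets, prevalence %.4f, distractors %.2f, seed %d\n",
              x$n_tweets, x$ade_prevalence, x$distractor_fraction, x$seed))
  invisible(x)
}

maybe_typo <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(word)
  i <- sample(n - 1L, 1L)
  paste0(substr(word, 1L, i - 1L), substr(word, i + 1L, i + 1L),
         substr(word, i, i), substr(word, i + 2L, n))
}

#' Generate a synthetic labeled tweet corpus
#'
#' Counts are exact (see \code{\link{corpus_spec}}); tweet order is
#' shuffled so ids carry no label information; a ground-truth table
#' records every planted drug and phrase.
#'
#' @param spec a \code{corpus_spec}.
#' @return object of class \code{synthetic_corpus}: list with
#'   \code{corpus} (data frame \code{tweet_id}, \code{text}, \code{label};
#'   label \code{NA} for distractors), \code{truth} (data frame
#'   \code{tweet_id}, \code{label}, \code{drug}, \code{phrase},
#'   \code{typo}, \code{phrase_dropped}) and \code{spec}.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_tweets
  n_dis <- round(n * spec$distractor_fraction)
  n_lab <- n - n_dis
  n_pos <- round(n_lab * spec$ade_prevalence)
  n_neg <- n_lab - n_pos
  emot <- default_emoticons()
  with_seed(spec$seed, {
    make_one <- function(kind) {
      drug <- NA_character_; phrase <- NA_character_
      typo <- FALSE; dropped <- FALSE
      fill <- function(k) if (k > 0) sample(spec$fillers, k, replace = TRUE)
                          else character(0)
      if (kind == "distractor") {
        toks <- fill(sample(4:10, 1L))
      } else {
        drug <- sample(spec$drug_vocab, 1L)
        drug_sur <- drug
        if (stats::runif(1) < spec$noise$typo) {
          drug_sur <- maybe_typo(sub(" .*", "", drug))
          typo <- drug_sur != sub(" .*", "", drug)
          if (grepl(" ", drug))
            drug_sur <- paste(drug_sur, sub("^\\S+ ", "", drug))
        }
        if (kind == "pos") {
          phrase <- sample(spec$ade_phrases, 1L)
          body <- phrase
          if (stats::runif(1) < spec$noise$phrase_dropout) {
            body <- sample(spec$benign_phrases, 1L)
            dropped <- TRUE
          }
        } else {
          body <- sample(spec$benign_phrases, 1L)
          if (kind == "pos") phrase <- body
        }
        toks <- c(fill(sample(0:3, 1L)), drug_sur, fill(sample(0:2, 1L)),
                  strsplit(body, " ")[[1L]], fill(sample(0:2, 1L)))
      }
      txt <- paste(toks, collapse = " ")
      if (stats::runif(1) < spec$noise$mention)
        txt <- paste0("@user", sample(999L, 1L), " ", txt)
      if (stats::runif(1) < spec$noise$emoticon)
        txt <- paste(txt, sample(emot, 1L))
      if (stats::runif(1) < spec$noise$url)
        txt <- paste0(txt, " http://t.co/",
                      paste(sample(letters, 6L, TRUE), collapse = ""))
      list(text = txt, drug = drug, phrase = phrase, typo = typo,
           dropped = dropped)
    }
    kinds <- c(rep("pos", n_pos), rep("neg", n_neg),
               rep("distractor", n_dis))
    rows <- lapply(kinds, make_one)
    ord <- sample.int(n)
    kinds <- kinds[ord]; rows <- rows[ord]
    ids <- sprintf("t%06d", seq_len(n))
    label <- ifelse(kinds == "pos", 1L,
                    ifelse(kinds == "neg", 0L, NA_integer_))
    corpus <- data.frame(tweet_id = ids,
                         text = vapply(rows, `[[`, "", "text"),
                         label = label, stringsAsFactors = FALSE)
    truth <- data.frame(tweet_id = ids, label = label,
                        drug = vapply(rows, `[[`, "", "drug"),
                        phrase = vapply(rows, `[[`, "", "phrase"),
                        typo = vapply(rows, `[[`, NA, "typo"),
                        phrase_dropped = vapply(rows, `[[`, NA, "dropped"),
                        stringsAsFactors = FALSE)
    structure(list(corpus = corpus, truth = truth, spec = spec),
              class = "synthetic_corpus")
  })
}

#' @exportS3Method base::print
print.synthetic_corpus <- function(x, ...) {
  lab <- x$corpus$label
  cat(sprintf("Synthetic corpus: %d tweets (%d positive, %d negative, %d distractor)\n",
              nrow(x$corpus), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
  invisible(x)
}

#' Canned fixture corpora for tests and examples
#'
#' Regenerates, bit-identically from embedded seeds, the small corpora
#' used across the test suite: a separable labeled corpus; a corpus whose
#' collocation graph gives one concept more than 15 tied neighbors (to
#' exercise pruning and tie-breaking); raw tweets including one that
#' normalizes to nothing; and tweets with multi-word drug names.
#'
#' @return named list with elements \code{separable}
#'   (\code{synthetic_corpus}), \code{tie_graph}
#'   (\code{tokenized_corpus}), \code{empty_norm} (raw corpus data
#'   frame) and \code{multiword} (raw corpus data frame).
#' @export
make_fixture_suite <- function() {
  separable <- generate_corpus(corpus_spec(n_tweets = 300L,
                                           ade_prevalence = 0.2,
                                           seed = 101L))
  # 20 distinct neighbors of "drugx", all weight 1 except four of weight 2
  nb <- sprintf("w%02d", 1:20)
  tie_tweets <- c(lapply(nb, function(w) c("drugx", w)),
                  lapply(nb[c(2, 5, 11, 17)], function(w) c(w, "drugx")))
  tie_graph <- structure(list(tweet_id = sprintf("g%03d", seq_along(tie_tweets)),
                              tokens = tie_tweets,
                              label = rep(NA_integer_, length(tie_tweets))),
                         class = "tokenized_corpus")
  empty_norm <- data.frame(
    tweet_id = c("e1", "e2", "e3"),
    text = c("https://x.yz", "took advil :(", "@bob https://t.co/q"),
    label = c(NA, 1L, NA), stringsAsFactors = FALSE)
  multiword <- data.frame(
    tweet_id = c("m1", "m2", "m3"),
    text = c("started vitamin d and fish oil today",
             "the fish swam in oil", "vitamin prices went up"),
    label = c(0L, NA, NA), stringsAsFactors = FALSE)
  list(separable = separable, tie_graph = tie_graph,
       empty_norm = empty_norm, multiword = multiword)
}
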
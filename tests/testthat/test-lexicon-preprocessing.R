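test_that("normalization applies the stated rules", {
  expect_identical(
    normalize_tweet("@john Advil gave me a headache :( http://t.co/abc"),
    c("<user>", "advil", "gave", "me", "a", "headache", "<emoticon>"))
  expect_identical(normalize_tweet("took 2 ADVIL!!"),
                   c("took", "2", "advil", "!", "!"))
  expect_identical(normalize_tweet("https://x.yz"), character(0))
  # non-ASCII special characters are removed, punctuation separated
  expect_identical(normalize_tweet("cafés, yes"), c("cafs", ",", "yes"))
  expect_error(normalize_tweet("   "), "empty")
})

test_that("normalization is idempotent on rejoined output", {
  texts <- c("@a B!! c:d http://t.co/x :(", "Advil&Tylenol... #meds",
             "plain words only", "weird   spacing\tand, marks;")
  for (tx in texts) {
    once <- normalize_tweet(tx)
    again <- normalize_tweet(paste(once, collapse = " "))
    expect_identical(again, once)
  }
  # property over generated corpora
  gen <- generate_corpus(corpus_spec(n_tweets = 100L, seed = 3L,
                                     noise = list(emoticon = 0.5, url = 0.3,
                                                  mention = 0.3)))
  for (tx in gen$corpus$text[1:40]) {
    once <- normalize_tweet(tx)
    expect_identical(normalize_tweet(paste(once, collapse = " ")), once)
  }
})

test_that("lexicon building performs case-insensitive set arithmetic with provenance", {
  lex <- build_lexicon(c("advil", "amen"), stoplist = "amen",
                       additions = "tylenol")
  expect_setequal(lex$names, c("advil", "tylenol"))
  expect_identical(lex$source[lex$names == "tylenol"], "corpus")
  expect_identical(lex$source[lex$names == "advil"], "base")

  lex2 <- build_lexicon("Advil", additions = "advil")
  expect_identical(length(lex2), 1L)

  expect_error(build_lexicon(character(0)), "non-empty")

  # the reference scale: base list of 4747 plus 141 corpus additions
  base <- sprintf("drug%04d", 1:4749)
  stop2 <- c("drug0001", "drug0002")
  adds <- sprintf("extra%03d", 1:141)
  big <- build_lexicon(base, stoplist = stop2, additions = adds)
  expect_identical(length(big), 4888L)
})

test_that("drug mention matching is exact, longest-first, and typo-blind", {
  lex <- build_lexicon(c("advil", "tylenol", "vitamin d", "vioxx"))
  hits <- find_drug_mentions(c("took", "advil", "and", "tylenol"), lex)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$name, c("advil", "tylenol"))

  expect_identical(nrow(find_drug_mentions(c("no", "drugs", "here"), lex)), 0L)
  expect_identical(nrow(find_drug_mentions(c("vioxe", "viox"), lex)), 0L)

  # multi-word longest match wins and spans are in range
  hits2 <- find_drug_mentions(c("my", "vitamin", "d", "dose"), lex)
  expect_identical(hits2$name, "vitamin d")
  expect_identical(hits2$start, 2L)
  expect_identical(hits2$end, 3L)
})

test_that("corpus drug filter retains exactly the drug-mentioning tweets", {
  lex <- build_lexicon(c("advil", "tylenol"))
  corpus <- data.frame(
    tweet_id = sprintf("t%d", 1:5),
    text = c("took advil today", "nice weather", "TYLENOL helps",
             "advil-free zone", "nothing here"),
    stringsAsFactors = FALSE)
  kept <- filter_corpus_by_drugs(corpus, lex)
  # "advil-free" splits to advil - free, so the mention survives
  expect_setequal(kept$tweet_id, c("t1", "t3", "t4"))

  all_drug <- corpus[c(1, 3), ]
  expect_identical(filter_corpus_by_drugs(all_drug, lex)$tweet_id,
                   all_drug$tweet_id)
})

test_that("filter count matches a planted 1000-tweet screening corpus", {
  spec <- corpus_spec(n_tweets = 1000L, ade_prevalence = 0.0956,
                      distractor_fraction = 0.7, seed = 42L)
  gen <- generate_corpus(spec)
  lex <- build_lexicon(spec$drug_vocab)
  kept <- filter_corpus_by_drugs(gen$corpus, lex)
  expect_identical(length(kept), 300L)
  # oracle: naive per-tweet membership scan agrees
  naive <- vapply(gen$corpus$text, function(tx) {
    tk <- normalize_tweet(tx)
    nrow(find_drug_mentions(tk, lex)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(sum(naive), 300L)
  expect_setequal(kept$tweet_id, gen$corpus$tweet_id[naive])
})

test_that("corpus and lexicon files round trip", {
  gen <- generate_corpus(corpus_spec(n_tweets = 30L, seed = 9L))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(gen$corpus, tf)
  back <- read_corpus(tf)
  expect_identical(back$tweet_id, gen$corpus$tweet_id)
  expect_identical(back$text, gen$corpus$text)
  expect_identical(back$label, gen$corpus$label)

  lex <- build_lexicon(c("Advil", "Vitamin D"), additions = "tylenol")
  lf <- withr::local_tempfile(fileext = ".txt")
  write_lexicon(lex, lf)
  expect_setequal(read_name_list(lf), lex$names)

  tok <- normalize_corpus(gen$corpus)
  kf <- withr::local_tempfile(fileext = ".tsv")
  write_tokens(tok, kf)
  tok2 <- read_tokens(kf)
  expect_identical(tok2$tokens, tok$tokens)
  expect_identical(tok2$label, tok$label)
})
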
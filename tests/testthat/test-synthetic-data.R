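test_that("generated corpora hit their planted counts exactly", {
  spec <- corpus_spec(n_tweets = 1000L, ade_prevalence = 0.0956, seed = 60L)
  gen <- generate_corpus(spec)
  expect_identical(sum(gen$corpus$label == 1L, na.rm = TRUE), 96L)
  expect_identical(nrow(gen$corpus), 1000L)
  expect_identical(anyNA(gen$corpus$label), FALSE)

  # with distractors: labeled prevalence exact, drug-filter pass rate exact
  spec2 <- corpus_spec(n_tweets = 500L, ade_prevalence = 0.2,
                       distractor_fraction = 0.4, seed = 61L)
  gen2 <- generate_corpus(spec2)
  lab <- gen2$corpus$label
  expect_identical(sum(is.na(lab)), 200L)
  expect_identical(sum(lab == 1L, na.rm = TRUE), 60L)
  lex <- build_lexicon(spec2$drug_vocab)
  expect_identical(length(filter_corpus_by_drugs(gen2$corpus, lex)), 300L)
})

test_that("the generator is bit-identical under a fixed seed", {
  spec <- corpus_spec(n_tweets = 200L, seed = 62L,
                      noise = list(typo = 0.1, url = 0.2, emoticon = 0.2))
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(spec)
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$truth, g2$truth)
})

test_that("construction guarantees separability at zero noise", {
  spec <- corpus_spec(n_tweets = 400L, ade_prevalence = 0.15, seed = 63L)
  gen <- generate_corpus(spec)
  tok <- normalize_corpus(gen$corpus)
  rule <- rule_classifier(spec$ade_phrases)
  m <- compute_metrics(tok$label, predict(rule, tok))
  expect_identical(m$f1, 1)
  # every positive has a drug mention too
  lex <- build_lexicon(spec$drug_vocab)
  pos <- tok[tok$label == 1L]
  expect_true(all(vapply(pos$tokens, function(t)
    nrow(find_drug_mentions(t, lex)) > 0L, logical(1))))
})

test_that("rule-based F1 degrades monotonically with phrase dropout", {
  f1_at <- function(rate) {
    spec <- corpus_spec(n_tweets = 600L, ade_prevalence = 0.2, seed = 64L,
                        noise = list(phrase_dropout = rate))
    gen <- generate_corpus(spec)
    tok <- normalize_corpus(gen$corpus)
    rule <- rule_classifier(spec$ade_phrases)
    compute_metrics(tok$label, predict(rule, tok))$f1
  }
  curve <- vapply(c(0, 0.3, 0.6), f1_at, 0)
  expect_identical(curve[1L], 1)
  expect_true(all(diff(curve) < 0))
})

test_that("invalid specs are rejected naming the offending field", {
  expect_error(corpus_spec(ade_prevalence = 1.5), "ade_prevalence")
  expect_error(corpus_spec(n_tweets = 0L), "n_tweets")
  expect_error(corpus_spec(distractor_fraction = -0.1),
               "distractor_fraction")
  expect_error(corpus_spec(noise = list(typo = 2)), "typo")
  expect_error(corpus_spec(noise = list(bogus = 0.1)), "bogus")
  expect_error(corpus_spec(drug_vocab = character(0)), "drug_vocab")
})

test_that("the fixture suite honours its contracts and regenerates identically", {
  fx <- make_fixture_suite()
  # a concept with more than 15 neighbors, for pruning
  g <- build_graph(fx$tie_graph)
  deg <- sum(g$edges$word_a == "drugx" | g$edges$word_b == "drugx")
  expect_gt(deg, 15L)
  # a tweet normalizing to empty
  norm_lens <- vapply(fx$empty_norm$text,
                      function(t) length(normalize_tweet(t)), 0L)
  expect_true(any(norm_lens == 0L))
  # multi-word drug names present and matched as spans
  lex <- build_lexicon(c("vitamin d", "fish oil"))
  tok <- normalize_corpus(fx$multiword)
  hits <- find_drug_mentions(tok$tokens[[1L]], lex)
  expect_setequal(hits$name, c("vitamin d", "fish oil"))
  # regenerates bit-identically
  fx2 <- make_fixture_suite()
  expect_identical(fx2$separable$corpus, fx$separable$corpus)
  expect_identical(fx2$tie_graph, fx$tie_graph)
})
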
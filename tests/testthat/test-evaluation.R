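test_that("positive-class metrics match hand computation", {
  # TP=3, FP=1, FN=2
  gold <- c(1, 1, 1, 1, 1, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0)
  m <- compute_metrics(gold, pred)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_equal(round(m$f1, 4), 0.6667)

  perfect <- compute_metrics(gold, gold)
  expect_identical(c(perfect$precision, perfect$recall, perfect$f1),
                   c(1, 1, 1))

  expect_warning(z <- compute_metrics(gold, rep(0, 8)), "precision")
  expect_identical(c(z$precision, z$f1), c(0, 0))

  expect_error(compute_metrics(c(1, 0), c(1)), "equal length")
})

test_that("the multi-run protocol reports means, population SD and best run", {
  vals <- list(list(precision = 0.5, recall = 0.7, f1 = 0.60),
               list(precision = 0.6, recall = 0.6, f1 = 0.62))
  rep2 <- multi_run(function(seed) vals[[seed]], n_runs = 2L, base_seed = 1L)
  expect_equal(unname(rep2$mean["f1"]), 0.61)
  expect_equal(unname(rep2$sd["f1"]), adetect:::pop_sd(c(0.60, 0.62)))

  one <- multi_run(function(seed) vals[[1L]], n_runs = 1L)
  expect_equal(unname(one$mean["f1"]), 0.60)
  expect_identical(unname(one$sd["f1"]), 0)
  expect_identical(select_best(one), 1L)

  f1s <- c(0.58, 0.63, 0.60)
  rep3 <- multi_run(function(seed) list(precision = 1, recall = 1,
                                        f1 = f1s[seed]), n_runs = 3L)
  expect_identical(select_best(rep3), 2L)
  tied <- multi_run(function(seed) list(precision = 1, recall = 1, f1 = 0.5),
                    n_runs = 3L)
  expect_identical(select_best(tied), 1L)

  tab <- format_eval_table(list(random = rep3, svm = tied))
  expect_identical(tab$model, c("random", "svm"))
  expect_match(tab$f1[2L], "^0\\.500 \\(0\\)$")
})

test_that("the train/validation split reproduces the 81.4/18.6 protocol", {
  tok <- separable_tok_corpus(n = 1000L, seed = 14L)
  sp <- split_corpus(tok, 0.814, seed = 5L)
  expect_identical(length(sp$train), 814L)
  expect_identical(length(sp$valid), 186L)
  expect_identical(sort(c(sp$train$tweet_id, sp$valid$tweet_id)),
                   sort(tok$tweet_id))
  # stratification keeps prevalence on both sides (within one tweet)
  q <- mean(tok$label)
  expect_lte(abs(mean(sp$train$label) - q), 1 / length(sp$train) + 1e-9)
  expect_lte(abs(mean(sp$valid$label) - q), 1 / length(sp$valid) + 1e-9)
  # seeded: same seed, same split
  sp2 <- split_corpus(tok, 0.814, seed = 5L)
  expect_identical(sp2$train$tweet_id, sp$train$tweet_id)
})

test_that("screening counts are nested and recover planted positives", {
  spec <- corpus_spec(n_tweets = 1000L, ade_prevalence = 0.2,
                      distractor_fraction = 0.5, seed = 30L)
  gen <- generate_corpus(spec)
  lex <- build_lexicon(spec$drug_vocab)
  rule <- rule_classifier(spec$ade_phrases)
  rep_ <- screen_corpus(gen$corpus, lex, rule)
  expect_identical(rep_$n_total, 1000L)
  expect_identical(rep_$n_drug, 500L)
  expect_lte(rep_$n_ade, rep_$n_drug)
  expect_lte(rep_$n_drug, rep_$n_total)
  # zero noise: the rule recovers the planted positives exactly
  expect_identical(rep_$n_ade, sum(gen$corpus$label == 1L, na.rm = TRUE))
  expect_setequal(rep_$ade_ids,
                  gen$corpus$tweet_id[!is.na(gen$corpus$label) &
                                      gen$corpus$label == 1L])

  # corpus without drug mentions: (N, 0, 0)
  no_drug <- data.frame(tweet_id = c("a", "b"),
                        text = c("nice day today", "so tired again"),
                        stringsAsFactors = FALSE)
  r0 <- screen_corpus(no_drug, lex, rule)
  expect_identical(c(r0$n_total, r0$n_drug, r0$n_ade), c(2L, 0L, 0L))
})
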
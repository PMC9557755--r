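make_emb <- function(tok, dim = 12L, seed = 88L)
  synthetic_embeddings(unique(unlist(tok$tokens)), dim = dim, seed = seed)

empty_nbs <- structure(list(), class = "neighbor_sets", k = 5L)

test_that("forward pass honors the architecture contract", {
  cfg <- tiny_clapa_cfg()
  params <- adetect:::clapa_init_params(cfg)
  set.seed(40)
  X <- matrix(rnorm(6 * cfg$input_dim), 6)
  z1 <- clapa_forward(X, params, cfg)
  expect_length(z1, 2L)
  expect_true(all(is.finite(z1)))
  # determinism
  expect_identical(clapa_forward(X, params, cfg), z1)
  # token-order sensitivity of the recurrent stack
  z_rev <- clapa_forward(X[6:1, ], params, cfg)
  expect_false(isTRUE(all.equal(z1, z_rev)))
  # dimension mismatch is an error
  expect_error(clapa_forward(matrix(rnorm(10), 2), params, cfg),
               "dimension")
  expect_error(adetect:::clapa_forward_batch(list(matrix(0, 0, cfg$input_dim)),
                                             params, cfg), "empty")
})

test_that("batched forward equals concatenated per-example forwards", {
  cfg <- tiny_clapa_cfg()
  params <- adetect:::clapa_init_params(cfg)
  set.seed(41)
  Xs <- lapply(c(3, 5, 2, 7), function(n)
    matrix(rnorm(n * cfg$input_dim), n))
  batch <- adetect:::clapa_forward_batch(Xs, params, cfg)$logits
  single <- t(vapply(Xs, clapa_forward, numeric(2L),
                     params = params, config = cfg))
  expect_equal(batch, single, tolerance = 1e-10)
})

test_that("training is seeded, deterministic, and validates its inputs", {
  tok <- separable_tok_corpus(n = 40L)
  emb <- make_emb(tok)
  cfg <- tiny_clapa_cfg()
  m1 <- clapa(tok, emb, empty_nbs, cfg)
  m2 <- clapa(tok, emb, empty_nbs, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, tok, type = "logits"),
                   predict(m2, tok, type = "logits"))

  # zero learning rate leaves parameters at initialization
  cfg0 <- tiny_clapa_cfg(learning_rate = 0)
  m0 <- clapa(tok, emb, empty_nbs, cfg0)
  expect_identical(m0$params, adetect:::clapa_init_params(cfg0))

  # single-class corpus is rejected
  pos_only <- tok[tok$label == 1L]
  expect_error(clapa(pos_only, emb, empty_nbs, cfg), "both classes")
  # mismatched embedding dimension is rejected
  expect_error(clapa(tok, make_emb(tok, dim = 5L), empty_nbs, cfg),
               "dimension")
})

test_that("configuration defaults match the reference setup", {
  cfg <- clapa_config()
  expect_identical(cfg$lstm_layers, 4L)
  expect_identical(cfg$input_dim, 300L)
  expect_identical(cfg$hidden_dim, 300L)
  expect_identical(cfg$attention_blocks, 3L)
  expect_identical(cfg$neighbor_k, 15L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_error(clapa_config(hidden_dim = 10L, attention_heads = 4L),
               "divisible")
})

test_that("trained CLAPA recovers the planted signal on a small corpus", {
  spec <- corpus_spec(n_tweets = 400L, ade_prevalence = 0.25, seed = 55L)
  gen <- generate_corpus(spec)
  tok <- normalize_corpus(gen$corpus)
  sp <- split_corpus(tok, 0.8, seed = 2L)
  lex <- build_lexicon(spec$drug_vocab)
  nbs <- prune_to_top_k(build_graph(sp$train), lex, k = 15L)
  emb <- synthetic_embeddings(unique(unlist(tok$tokens)), dim = 24L,
                              seed = 66L)
  cfg <- clapa_config(lstm_layers = 2L, input_dim = 24L, hidden_dim = 16L,
                      attention_blocks = 2L, attention_heads = 2L,
                      epochs = 12L, batch_size = 8L, max_length = 24L,
                      seed = 3L)
  m <- clapa(sp$train, emb, nbs, cfg)
  mt <- compute_metrics(sp$valid$label, predict(m, sp$valid))
  expect_gte(mt$f1, 0.9)
  # beats the weighted-random baseline by a wide margin
  rnd <- random_baseline(sp$train)
  mr <- compute_metrics(sp$valid$label, predict(rnd, sp$valid, seed = 4L))
  expect_gte(mt$f1 - mr$f1, 0.5)
})
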
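test_that("logit fusion obeys its algebraic contract", {
  fc <- list(W = matrix(0, 4, 2), b = c(0.3, -0.4))
  fz <- fuse(c(1, 2), c(-1, 0.5), fc)
  expect_length(fz$z_final, 2L)
  # all-zero weights: output is the bias regardless of inputs
  expect_identical(fz$z_final, fc$b)
  fz2 <- fuse(c(100, -7), c(3, 3), fc)
  expect_identical(fz2$z_final, fc$b)
  # softmax of the fused logits sums to one
  expect_equal(sum(fz$prob), 1, tolerance = 1e-12)
  expect_true(fz$class %in% c(0L, 1L))

  # CLAPA-only projection returns z_clapa exactly
  proj <- adetect:::clapa_only_projection()
  z <- fuse(c(0.7, -1.2), c(5, 5), proj)
  expect_identical(z$z_final, c(0.7, -1.2))

  expect_error(fuse(c(1, 2, 3), c(0, 0), fc), "length 2")
})

test_that("baCLAPA with the CLAPA-only projection reproduces standalone CLAPA", {
  spec <- corpus_spec(n_tweets = 120L, ade_prevalence = 0.25, seed = 57L)
  gen <- generate_corpus(spec)
  tok <- normalize_corpus(gen$corpus)
  lex <- build_lexicon(spec$drug_vocab)
  nbs <- prune_to_top_k(build_graph(tok), lex, k = 15L)
  emb <- synthetic_embeddings(unique(unlist(tok$tokens)), dim = 12L,
                              seed = 91L)
  ccfg <- tiny_clapa_cfg()
  ecfg <- tiny_encoder_cfg(epochs = 1L)
  alone <- clapa(tok, emb, nbs, ccfg)
  joint <- baclapa(tok, emb, nbs, ccfg, ecfg, fusion = "clapa_only")
  expect_identical(joint$clapa$params, alone$params)
  expect_identical(unname(predict(joint, tok, type = "logits")),
                   unname(predict(alone, tok, type = "logits")))
  expect_identical(predict(joint, tok), predict(alone, tok))
})

test_that("joint training validates resources and is seed-deterministic", {
  tok <- separable_tok_corpus(n = 40L)
  emb <- synthetic_embeddings(unique(unlist(tok$tokens)), dim = 12L,
                              seed = 92L)
  nbs <- structure(list(), class = "neighbor_sets", k = 5L)
  ccfg <- tiny_clapa_cfg(epochs = 1L)
  ecfg <- tiny_encoder_cfg(epochs = 1L)
  expect_error(baclapa(tok, neighbors = nbs, clapa_cfg = ccfg,
                       encoder_cfg = ecfg), "embedding")
  expect_error(baclapa(tok, embeddings = emb, clapa_cfg = ccfg,
                       encoder_cfg = ecfg), "neighbor")
  m1 <- baclapa(tok, emb, nbs, ccfg, ecfg)
  m2 <- baclapa(tok, emb, nbs, ccfg, ecfg)
  expect_identical(predict(m1, tok, type = "logits"),
                   predict(m2, tok, type = "logits"))
  # predictions are always 0/1 and fused probabilities normalize
  p <- predict(m1, tok)
  expect_true(all(p %in% c(0L, 1L)))
  pr <- predict(m1, tok, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("an uninformative encoder stack leaves baCLAPA at CLAPA-level accuracy", {
  # encoder frozen at random initialization: its logits carry no signal,
  # so jointly trained fusion should match standalone CLAPA (both near
  # perfect on the separable corpus) across seeds
  spec <- corpus_spec(n_tweets = 400L, ade_prevalence = 0.25, seed = 58L)
  gen <- generate_corpus(spec)
  tok <- normalize_corpus(gen$corpus)
  sp <- split_corpus(tok, 0.8, seed = 3L)
  lex <- build_lexicon(spec$drug_vocab)
  nbs <- prune_to_top_k(build_graph(sp$train), lex, k = 15L)
  emb <- synthetic_embeddings(unique(unlist(tok$tokens)), dim = 16L,
                              seed = 93L)
  f_alone <- numeric(0); f_frozen <- numeric(0)
  for (s in 1:3) {
    ccfg <- clapa_config(lstm_layers = 2L, input_dim = 16L,
                         hidden_dim = 12L, attention_blocks = 1L,
                         attention_heads = 2L, epochs = 8L,
                         batch_size = 8L, max_length = 24L, seed = s)
    ecfg <- tiny_encoder_cfg(epochs = 1L, seed = s)
    a <- clapa(sp$train, emb, nbs, ccfg)
    b <- baclapa(sp$train, emb, nbs, ccfg, ecfg, freeze_encoder = TRUE)
    f_alone <- c(f_alone,
                 compute_metrics(sp$valid$label, predict(a, sp$valid))$f1)
    f_frozen <- c(f_frozen,
                  compute_metrics(sp$valid$label, predict(b, sp$valid))$f1)
  }
  spread <- max(adetect:::pop_sd(f_alone), adetect:::pop_sd(f_frozen), 0.05)
  expect_lte(abs(mean(f_alone) - mean(f_frozen)), spread + 0.05)
})
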
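# Shared builders for the test suite.  Everything is generated in code,
# seeded, and small.

tok_corpus <- function(token_lists, labels = rep(NA_integer_, length(token_lists))) {
  structure(list(tweet_id = sprintf("x%03d", seq_along(token_lists)),
                 tokens = token_lists,
                 label = as.integer(labels)),
            class = "tokenized_corpus")
}

# Brute-force quadratic co-occurrence counter: the oracle for build_graph.
brute_cooc <- function(token_lists) {
  counts <- new.env(parent = emptyenv())
  for (t in token_lists) {
    if (length(t) < 2L) next
    for (i in seq_len(length(t) - 1L)) {
      a <- t[i]; b <- t[i + 1L]
      if (a == b) next
      key <- paste(min(a, b), max(a, b), sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- sort(ls(counts))
  if (length(keys) == 0L)
    return(data.frame(word_a = character(0), word_b = character(0),
                      weight = integer(0)))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(word_a = vapply(parts, `[`, "", 1L),
             word_b = vapply(parts, `[`, "", 2L),
             weight = vapply(keys, function(k) counts[[k]], 0L,
                             USE.NAMES = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random token corpus for property tests.
random_tok_corpus <- function(n_tweets, vocab_size = 12L, max_len = 8L) {
  vocab <- sprintf("v%02d", seq_len(vocab_size))
  lapply(seq_len(n_tweets), function(i)
    sample(vocab, sample.int(max_len, 1L), replace = TRUE))
}

# Tiny CLAPA config used throughout the unit tests.
tiny_clapa_cfg <- function(...) {
  args <- utils::modifyList(
    list(lstm_layers = 2L, input_dim = 12L, hidden_dim = 8L,
         attention_blocks = 2L, attention_heads = 2L,
         neighbor_k = 5L, epochs = 2L, batch_size = 8L,
         max_length = 16L, seed = 7L),
    list(...))
  do.call(clapa_config, args)
}

tiny_encoder_cfg <- function(...) {
  args <- utils::modifyList(
    list(preset = "tiny", layers = 1L, hidden_dim = 16L, heads = 2L,
         ffn_dim = 32L, epochs = 2L, batch_size = 8L,
         max_length = 32L, seed = 7L),
    list(...))
  do.call(encoder_config, args)
}

# Small labeled corpus where positives carry an unmistakable signal.
separable_tok_corpus <- function(n = 60L, seed = 5L) {
  spec <- corpus_spec(n_tweets = n, ade_prevalence = 0.3, seed = seed)
  gen <- generate_corpus(spec)
  normalize_corpus(gen$corpus)
}
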
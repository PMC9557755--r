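test_that("adjacency counting matches hand-enumerated examples", {
  g <- build_graph(list(c("a", "b", "a")))
  expect_identical(g$edges$weight, 2L)
  expect_identical(g$edges$word_a, "a")
  expect_identical(g$edges$word_b, "b")

  g2 <- build_graph(list(c("advil", "headache"), c("advil", "nausea"),
                         c("headache", "advil")))
  lex <- build_lexicon("advil")
  nb <- prune_to_top_k(g2, lex, k = 15L)
  expect_identical(nb$advil$word, c("headache", "nausea"))
  expect_identical(nb$advil$weight, c(2L, 1L))

  g3 <- build_graph(list("solo", "another"))
  expect_identical(nrow(g3$edges), 0L)
  expect_setequal(g3$nodes, c("solo", "another"))

  # self-adjacency of a repeated token is not an edge
  g4 <- build_graph(list(c("very", "very", "bad")))
  expect_identical(g4$edges$word_a, "bad")
  expect_identical(sum(g4$edges$weight), 1L)

  expect_error(build_graph(list()), "empty")
})

test_that("graph equals the brute-force quadratic counter on random corpora", {
  set.seed(20)
  for (rep in 1:25) {
    corp <- random_tok_corpus(sample.int(100L, 1L))
    g <- build_graph(corp)
    oracle <- brute_cooc(corp)
    expect_identical(g$edges$word_a, oracle$word_a)
    expect_identical(g$edges$word_b, oracle$word_b)
    expect_identical(g$edges$weight, oracle$weight)
    # conservation: total edge weight = number of counted adjacent pairs
    pairs <- sum(vapply(corp, function(t) {
      if (length(t) < 2L) return(0L)
      sum(t[-length(t)] != t[-1L])
    }, 0L))
    expect_identical(sum(g$edges$weight), pairs)
  }
})

test_that("graph construction is invariant to tweet order", {
  set.seed(21)
  corp <- random_tok_corpus(40L)
  g1 <- build_graph(corp)
  g2 <- build_graph(corp[sample(length(corp))])
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$nodes, g2$nodes)
})

test_that("pruning keeps the k strongest neighbors with deterministic ties", {
  fx <- make_fixture_suite()
  g <- build_graph(fx$tie_graph)
  lex <- build_lexicon("drugx")
  nb <- prune_to_top_k(g, lex, k = 15L)$drugx
  expect_identical(nrow(nb), 15L)
  # all retained weights >= all dropped weights
  all_nb <- prune_to_top_k(g, lex, k = 100L)$drugx
  expect_gte(min(nb$weight), max(all_nb$weight[-(1:15)]))
  # weight-2 neighbors first, then lexicographic among the tied weight-1
  expect_identical(nb$weight[1:4], rep(2L, 4L))
  expect_identical(nb$word[1:4], sort(nb$word[1:4]))
  ones <- nb$word[nb$weight == 1L]
  expect_identical(ones, sort(ones))

  # bit-for-bit reproducible across runs
  nb2 <- prune_to_top_k(build_graph(fx$tie_graph), lex, k = 15L)$drugx
  expect_identical(nb, nb2)

  # fewer neighbors than k: all retained; absent concept: empty set
  g2 <- build_graph(list(c("advil", "x"), c("advil", "y"), c("z", "advil")))
  lex2 <- build_lexicon(c("advil", "missing"))
  nbs <- prune_to_top_k(g2, lex2, k = 15L)
  expect_identical(nrow(nbs$advil), 3L)
  expect_null(nbs$missing)

  # exhaustive-sort oracle on a random graph
  set.seed(22)
  corp <- random_tok_corpus(60L)
  corp <- c(corp, list(c("drugy", "v01"), c("drugy", "v02"), c("v03", "drugy")))
  g3 <- build_graph(corp)
  nb3 <- prune_to_top_k(g3, build_lexicon("drugy"), k = 2L)$drugy
  e <- g3$edges
  touch <- e$word_a == "drugy" | e$word_b == "drugy"
  w <- e$weight[touch]
  other <- ifelse(e$word_a[touch] == "drugy", e$word_b[touch], e$word_a[touch])
  ord <- order(-w, other)
  expect_identical(nb3$word, other[ord][1:2])
  expect_identical(nb3$weight, w[ord][1:2])
})

test_that("graph and neighbor sets serialize and round trip", {
  set.seed(23)
  corp <- c(random_tok_corpus(30L), list("isolated"))
  g <- build_graph(corp)
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_graph(g, gf)
  g2 <- read_graph(gf)
  expect_identical(g2$edges$word_a, g$edges$word_a)
  expect_identical(g2$edges$weight, g$edges$weight)
  expect_identical(g2$nodes, g$nodes)

  nbs <- prune_to_top_k(g, build_lexicon(c("v01", "v05")), k = 3L)
  nf <- withr::local_tempfile(fileext = ".tsv")
  write_neighbor_sets(nbs, nf)
  df <- read.delim(nf, stringsAsFactors = FALSE)
  expect_true(all(df$rank >= 1 & df$rank <= 3))
  expect_setequal(unique(df$concept), names(nbs)[vapply(nbs, nrow, 0L) > 0])
})
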
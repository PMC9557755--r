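# adetect

Detection of adverse drug event (ADE) mentions in tweet-like short texts,
for pharmacovigilance work that mines social media. An ADE tweet must
mention both an adverse event and a drug by name; the corpora this task is
run on are heavily imbalanced (roughly 9% positives among drug-mentioning
tweets), so everything here reports positive-class precision, recall and
F1.

The package implements, end to end and in plain R:

* **Preprocessing and lexicon screening** — tweet normalization
  (punctuation separation, URL removal, `<user>`/`<emoticon>`
  placeholders, lowercasing), a drug-name lexicon built from a base
  reference list plus corpus additions minus a stoplist of everyday-word
  collisions, exact longest-match mention matching, and the two-stage
  screening pipeline (drug filter, then classifier).
* **CLAPA** — a collocated LSTM with attentive pooling and aggregated
  representation. A collocation graph over the training corpus (nodes =
  words, edge weights = adjacent co-occurrence counts) is pruned to the
  top *k* = 15 neighbors per medical concept; concept embeddings are
  augmented with the weight-proportional average of their neighbors'
  vectors, then fed through a 4-layer LSTM (300-d inputs), 3 residual
  multi-head attention blocks, max pooling concatenated with attentive
  pooling, and a fully connected layer to 2-class logits. Trained with
  Adam (learning rate 0.001) and cross-entropy.
* **A contextual encoder** — a transformer sequence classifier over
  subword pieces with `[CLS]`/`[SEP]` markers. The `"base"` preset has
  the standard uncased shape (12 layers, 768 hidden, 12 heads, learning
  rate 5e-5); the `"tiny"` preset (2 layers, 64 hidden, 2 heads) is the
  same architecture at desk scale so the whole pipeline trains and tests
  with no pretrained download.
* **baCLAPA** — logit-level fusion of the two stacks: with z_CLAPA and
  z_BERT the 2-class logits of each stack,

      z_final = FC([z_CLAPA ; z_BERT]),   ŷ = argmax softmax(z_final)

  where FC is a single fully connected 4→2 layer, trained jointly with
  both stacks under one cross-entropy objective.
* **Baselines and protocol** — a weighted random classifier (predicts
  positive with probability equal to the training prevalence), a
  linear-kernel SVM over tf-idf word-n-gram (up to trigram) features, the
  81.4%/18.6% train/validation split, the 10-run mean ± SD report with
  best-run selection, and a seeded synthetic-corpus generator with
  planted ADE structure for testing every stage.

## Worked example

```r
library(adetect)

spec <- corpus_spec(n_tweets = 600, ade_prevalence = 0.2, seed = 42)
gen  <- generate_corpus(spec)
gen
#> Synthetic corpus: 600 tweets (120 positive, 480 negative, 0 distractor)

tok <- normalize_corpus(gen$corpus)
sp  <- split_corpus(tok, train_frac = 0.814, seed = 1)

lex   <- build_lexicon(spec$drug_vocab)
graph <- build_graph(sp$train)
graph
#> Collocation graph: 112 nodes, 1280 edges, total weight 3621
nbs <- prune_to_top_k(graph, lex, k = 15)

emb <- synthetic_embeddings(unique(unlist(tok$tokens)), dim = 24, seed = 7)
cfg <- clapa_config(lstm_layers = 2, input_dim = 24, hidden_dim = 16,
                    attention_blocks = 2, attention_heads = 2,
                    epochs = 10, batch_size = 8, max_length = 24, seed = 3)
fit <- clapa(sp$train, emb, nbs, cfg)
fit
#> CLAPA classifier
#>   2 LSTM layers (input 24, hidden 16), 2 attention blocks (2 heads)
#>   neighbor k = 15; trained 10 epochs (final loss 0.0051)

compute_metrics(sp$valid$label, predict(fit, sp$valid))
#> P = 1.0000  R = 1.0000  F1 = 1.0000  (TP 23, FP 0, FN 0, TN 89)

rnd <- random_baseline(sp$train)
multi_run(function(seed)
  compute_metrics(sp$valid$label, predict(rnd, sp$valid, seed = seed)),
  n_runs = 10, base_seed = 1)
#> Average performance of 10 runs
#>   Precision 0.205 (0.088)  Recall 0.170 (0.06)  F1 0.184 (0.07)
```

The synthetic corpus plants a drug name in every labeled tweet and an
adverse-event phrase in exactly the positives, so a trained CLAPA
separates the classes perfectly while the weighted random baseline stays
near the 0.2 prevalence — the expected ordering for this task. On this
corpus a `text_encoder()` (tiny preset) and `baclapa()` fit behave the
same way, and `screen_corpus()` runs the drug-filter → classifier
pipeline over a raw corpus.

A thin command-line interface over these functions is installed at
`inst/cli/ade.R` (`simulate`, `preprocess`, `build-graph`, `train`,
`evaluate`, `screen`).

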
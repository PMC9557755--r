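---
title: "Methods: collocation-augmented and fused classifiers for ADE tweets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collocation-augmented and fused classifiers for ADE tweets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models it implements,
the choices made where the design was genuinely open, and what the test
suite does and does not establish.

## The task and its structure

The unit of analysis is a tweet-length text with a binary label: does it
mention an adverse drug event? By convention an ADE tweet must name both
a drug and an adverse event, with no causality claim. Two structural
facts drive every design decision: the texts are short and noisy (URLs,
user mentions, emoticons, free-form punctuation), and the positive class
is rare — roughly 9.6% of drug-mentioning tweets in the training regime
this package emulates. All evaluation is therefore positive-class
precision, recall and F1, never accuracy.

## Preprocessing

`normalize_tweet()` applies, in order: removal of URL-shaped substrings;
replacement of whitespace-delimited `@...` tokens by `<user>`;
replacement of table-listed emoticons by `<emoticon>`; removal of
special characters (defined as non-ASCII and control characters — the
narrowest reading that preserves words and punctuation); separation of
punctuation marks into standalone tokens; lowercasing. The tokenizer is
deliberately a whitespace split after punctuation spacing — no external
tokenizer is used. Numbers and hashtag bodies pass through unchanged.
User mentions are *replaced* rather than removed, because the position
of a mention carries sequence information for the recurrent stack.

Normalization is idempotent (re-normalizing its rejoined output is a
fixed point); this is enforced by tests and constrains the emoticon
table — an emoticon whose surface form lowercases to a plain
alphabetic token would break the property, so the shipped table avoids
such entries. A tweet that normalizes to nothing (e.g. a bare URL)
yields a zero-length token vector and the caller decides whether to
drop it; `normalize_corpus()` drops by default.

The drug lexicon is a case-folded set union: base reference names, minus
a stoplist of everyday-word collisions ("amen", "heather"), plus
corpus-derived additions, with per-name provenance. Mention matching is
exact after case folding, longest-match-first over token n-grams (so
multi-word names like "vitamin d" match as spans); typos deliberately do
not match — the original pipeline excluded typo'd tweets rather than
correcting them, and this package follows that.

## The collocation graph

Nodes are the unique words of the training corpus; an undirected edge
weight counts how often two words occur strictly adjacently (distance
one, either order), never across tweet boundaries. Three choices were
open and are fixed as follows:

* **"Closest" neighbors** are those with the highest adjacency count.
  The upstream description never defines its distance; the count is the
  minimal reading consistent with an adjacency-edge graph. PMI-weighted
  or embedding-distance variants are out of scope.
* **Ties** at the k-th rank break by lexicographic word order, making
  pruned neighbor sets reproducible bit for bit.
* **Self-loops** from immediate word repetition ("very very") are
  excluded: self-adjacency carries no neighborhood information.

Neighbor sets are computed only for lexicon concepts, with *k* = 15 by
default. A concept absent from the graph (including every multi-word
name, whose parts are separate nodes) simply has no neighbor set and
falls back to its plain embedding.

## CLAPA

Each token maps to its embedding vector; a concept token additionally
receives the weight-proportional average of its pruned neighbors'
vectors, added to its own (for neighbors with weights \(w_i\) and
vectors \(v_i\), the augmentation term is
\(\sum_i w_i v_i / \sum_i w_i\)). The combination operator lives behind
`embed_with_neighborhood()` as a single swappable function; addition was
chosen because it preserves the embedding scale and reduces exactly to
plain lookup when the neighbor map is empty — an ablation identity the
tests rely on.

The sequence then passes through:

1. a stack of LSTM layers (default 4, input dimension 300, hidden size
   equal to the input size — the configuration names one "input size",
   and hidden = input is the reading adopted; `hidden_dim` is exposed
   separately so smaller models can be trained),
2. residual multi-head self-attention blocks (default 3). Each block is
   attention plus a residual connection only — no feed-forward sublayer
   or layer normalization — as the minimal reading of "attention
   layers"; heads default to 6, the smallest natural divisor of 300
   giving 50-dimensional heads,
3. pooling over time: the elementwise max over positions concatenated
   with an attentive (softmax-weighted) average, matching the "attentive
   pooling" in the model's name; a learned score vector produces the
   weights,
4. a fully connected projection to 2 logits (non-ADE, ADE).

Training is Adam at learning rate 0.001 with cross-entropy, epochs 10,
batch size 32, no class weighting, no dropout, no early stopping — all
configurable via `clapa_config()`. Embedding vectors are fixed during
training (they stand for a pretrained table). Sequences are truncated at
64 tokens and padded with zero vectors per batch; because the LSTM is
causal and pooling/attention only ever see the valid positions, padding
is exactly inert, and the batched forward pass equals per-example
forward passes (a tested invariance).

## The contextual encoder

`text_encoder()` is a transformer classifier over subword pieces with
`[CLS]`/`[SEP]` boundary markers: learned token embeddings plus fixed
sinusoidal positions, post-norm blocks (attention + residual + layer
norm, feed-forward + residual + layer norm), and a linear head on the
`[CLS]` state. The subword vocabulary is built from the training corpus:
frequent whole words, plus every seen character both word-initially and
as a `##` continuation, so any in-alphabet word decomposes greedily and
detokenization recovers the lowercased input up to whitespace (a tested
round trip). Inputs longer than `max_length` (default 128 pieces) are
truncated with a warning rather than an error.

The `"base"` preset carries the standard uncased shape — 12 layers, 768
hidden, 12 heads, learning rate 5e-5, 3 epochs — and can start from
supplied parameters. The `"tiny"` preset (2 layers, 64 hidden, 2 heads,
feed-forward 256) is the same architecture behind the same interface,
randomly initialized. Its learning rate is 1e-3, not 5e-5: the base rate
is a *fine-tuning* rate appropriate when starting from pretrained
weights, and a from-scratch tiny model at 5e-5 would barely move in a
few epochs. For the ambiguous question of whether fine-tuning updates
all layers or only the classification head, the default is all layers,
with `train = "head"` as the alternative.

## baCLAPA

Both stacks consume the same normalized text (the encoder applies its
own subword tokenization downstream). Each stack produces 2-class
logits; the fused head is a single fully connected layer with bias and
no nonlinearity mapping the concatenated 4-vector to the final logits,
followed by softmax and argmax. Fusion is at the logit level only —
hidden-state fusion is explicitly out of scope.

Training is joint and end to end: one cross-entropy objective on the
fused logits, gradients flowing into both stacks, each stack keeping its
own Adam state and learning rate ("independently learns" is read as
architectural independence — no shared weights — not as frozen stacks;
`freeze_encoder = TRUE` provides the alternative reading, and staged or
alternating schedules were not adopted). The joint loop replicates the
standalone CLAPA fit exactly — same initialization stream, same epoch
shuffling — so that freezing the fusion layer to the projection
`W = [I; 0], b = 0` makes the whole system *bit-identical* to standalone
CLAPA. This reduction is the strongest correctness oracle available for
the fusion code and is asserted in the tests.

## Baselines

The weighted random baseline predicts positive with probability equal to
the training prevalence \(q\); its expected precision and recall both
equal \(q\), hence expected F1 \(\approx q\) — the analytic anchor used
by the acceptance script. The SVM baseline uses tf-idf over word n-grams
up to trigrams (word, not character, n-grams — the standard reading for
tf-idf tweet baselines; a character mode sits behind a flag), smoothed
idf \(\log((1+N)/(1+\mathrm{df})) + 1\), L2-normalized rows, and a
linear-kernel SVM with library defaults. The fit is deterministic, so
its multi-run SD is exactly zero — itself a tested property.

## Evaluation protocol

`compute_metrics()` reports positive-class P/R/F1 with zero denominators
reported as 0 plus a warning. `multi_run()` repeats a seeded run
function, varying the seed only (initialization, not the split), and
reports means with the *population* SD (divisor \(n\)): the runs are the
entire population being summarized, not a sample from a larger one.
`select_best()` takes the maximal-F1 run, earliest seed on ties.
`split_corpus()` is random, seeded and stratified, with the training
count exactly `round(n * 0.814)` and per-class counts by largest
remainder, reproducing the 81.4%/18.6% protocol on any corpus size.
`screen_corpus()` chains the drug filter and a classifier and reports
the nested stage counts.

## The synthetic generator

`generate_corpus()` emulates the statistical frame of the real training
data: short texts; ADE prevalence 2362/24700 ≈ 0.0956 among labeled
(drug-bearing) tweets by default; every positive contains at least one
drug token and one adverse-event phrase; every labeled negative a drug
token and a benign phrase; optional drug-free distractors for screening
tests; optional noise (drug-surface typos, emoticon/URL/mention
injection, and phrase dropout, which is label noise by construction).
Counts are exact rather than Bernoulli — positives number
`round(n_labeled * prevalence)` — so fixture assertions are
deterministic. Prevalence is defined over labeled tweets (not the full
corpus) because the labeled universe in the emulated regime is
drug-mentioning tweets; with no distractors the two definitions
coincide. Phrase vocabularies are constructed so that no negative can
contain an adverse-event phrase as a contiguous subsequence, which makes
the zero-noise corpus perfectly separable by a drug-AND-phrase rule
(`rule_classifier()`), a property the tests verify along with its
monotone degradation under phrase dropout.

What the generator does *not* emulate: real lexical diversity, spelling
variation beyond single transpositions, topic drift, sarcasm, negation
("didn't give me a headache"), or any distributional shift between
training and evaluation corpora. Passing tests on synthetic corpora
therefore demonstrate that the implementations learn and evaluate
correctly, not that they would reach any particular score on real
social-media data — the original study's headline numbers require its
restricted corpora and pretrained weights, and no claim about them is
made here.

## Numerical choices and degenerate inputs

* Initialization: Xavier-uniform for weight matrices, zeros for biases,
  forget-gate bias 1 (standard stabilization for short sequences),
  N(0, 0.02²) for encoder token embeddings; all under a seeded RNG whose
  state is restored afterwards, so fits never perturb the caller's
  simulations.
* Determinism: no dropout anywhere; shuffling derives from
  `seed + epoch`; repeated fits with one seed are bit-identical, which
  the tests assert.
* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-12; layer-norm epsilon is 1e-5.
* Argmax prediction ties (exactly equal logits) resolve to the negative
  class deterministically.
* Degenerate inputs error early with named messages: empty corpora,
  single-class training labels, embedding/config dimension mismatches,
  missing fusion resources, invalid generator fields.
* All backward passes are verified against central finite differences
  (the max-pool argmax makes the loss only piecewise smooth; checks are
  run at generic points).

## Problem sizes in the test suite

The suite trains desk-scale models: unit tests use 2-layer stacks with
8–16 hidden units on corpora of a few hundred tweets; the end-to-end
signal-recovery test uses a 2,000-tweet corpus at prevalence 0.0956 with
300-dimensional synthetic embeddings, a hidden size of 60 for CLAPA (4
LSTM layers, 3 attention blocks, 6 heads, 4 epochs) and the tiny encoder
preset (6 epochs). These sizes were chosen as the smallest at which the
planted signal is recovered comfortably (F1 ≥ 0.9 with margin); the
architecture defaults remain the full-scale ones.

## Known limitations

* The encoder's base preset is architecture-complete but there is no
  bundled pretrained weight set; without one it trains from scratch,
  which is not meaningful at the 12×768 scale on CPU.
* Multi-word lexicon concepts receive no neighborhood augmentation
  (their parts are separate graph nodes).
* The SVM decision threshold is the libsvm default; no class-weight or
  kernel search is performed, by design.
* Typos in drug names are never matched or corrected; screening recall
  on typo-noised corpora degrades accordingly (and observably, via the
  generator's typo rate).
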
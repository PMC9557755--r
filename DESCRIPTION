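Package: adetect
Title: Adverse Drug Event Detection in Short Social-Media Texts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifiers for detecting mentions of adverse drug events
    (ADEs) in tweet-like short texts. Implements a collocation-graph
    augmented recurrent network with multi-head attention and attentive
    pooling (CLAPA), a transformer encoder classifier, and a logit-level
    fusion of the two (baCLAPA), together with tweet normalization, a
    drug-name lexicon screening pipeline, tf-idf/SVM and weighted-random
    baselines, a multi-run evaluation protocol for the minority class,
    and a seeded synthetic-corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
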
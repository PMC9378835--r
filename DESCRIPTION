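Package: liwcnn
Title: Lexicon-Weighted Convolutional Triage of Mental-Health Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns social-media posts to four escalating mental-health risk
    categories (green, amber, red, crisis) with a convolutional text classifier
    whose input word vectors are scaled by lexicon-derived attention weights.
    Word classes from a LIWC-style dictionary are ranked by the standard
    deviation of their max-normalized per-category frequencies; the top-k
    classes drive per-word attention weights and per-post linguistic feature
    vectors.  Includes the full pipeline: '.dic' lexicon parsing with
    trailing-wildcard matching, corpus preprocessing (link replacement,
    corpus-driven emoji polarity labeling, character filtering, padding),
    skip-gram word embeddings, the attention CNN with max-over-time pooling
    and its three comparison baselines, mini-batch training with
    validation-peak model selection, CLPsych-style triage metrics, and a
    synthetic corpus generator with planted lexical signal for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
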
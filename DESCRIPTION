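Package: curribatch
Title: Curriculum Batching for Long-Tailed Multi-Label Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and applying curriculum batching in
    minibatch gradient descent for multi-label text classification under
    long-tailed label distributions, as arises in automatic ICD coding of
    clinical notes. Provides three batch-set samplers -- plain shuffling,
    stratified sampling with replacement (uniform label exposure), and
    probability sampling with replacement (global-distribution-matched
    label exposure) -- together with an easy-to-hard curriculum schedule
    that sequences them, Kullback-Leibler and Jensen-Shannon batch-set
    difficulty diagnostics, micro/macro and long-tailed-label evaluation
    metrics, a reference convolutional text classifier trained by Adam,
    a text preprocessing pipeline (cleaning, TF-IDF vocabulary
    truncation, splitting), and a seeded generator of synthetic
    long-tailed multi-label corpora for end-to-end experimentation.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
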
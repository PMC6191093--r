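Package: sevcnn
Title: Severity Classification Workbench for Psychiatric Evaluation Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for ordinal severity classification (ABSENT, MILD,
    MODERATE, SEVERE) of positive-valence symptoms in initial psychiatric
    evaluation records. Generates seeded synthetic corpora that emulate the
    three text formats of such records (narrative, attribute-value lists,
    question-answer templates), normalises semi-structured content
    (spell correction, merged-token refinement, question-to-short-form
    normalisation), trains convolutional neural network document classifiers
    (single-region 1-max, parallel multi-region, and chunk-max pooling
    architectures, with one-hot, random, or pretrained word representations)
    alongside bag-of-words baselines with information-gain feature selection,
    and scores predictions with ordinal metrics: per-class mean absolute
    error, macro-averaged MAE, and normalised macro-averaged MAE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
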
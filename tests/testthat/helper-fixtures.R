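# Fixtures are generated in code; nothing is read from disk except the
# package's own bundled extdata.

# A corpus built directly from raw texts (one narrative segment each);
# handy for constructing exact token streams in unit tests.
corpus_from_texts <- function(texts, labels = NULL, ids = NULL) {
  n <- length(texts)
  labels <- labels %||% rep(NA_character_, n)
  ids <- ids %||% sprintf("t%03d", seq_len(n))
  psych_corpus(lapply(seq_len(n), function(i) {
    psychiatric_record(
      ids[i],
      data.frame(kind = "narrative", text = texts[i], stringsAsFactors = FALSE),
      labels[i]
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tok_from_texts <- function(texts, labels = NULL, ...) {
  preprocess_corpus(corpus_from_texts(texts, labels), spell = FALSE, ...)
}

# Small separable world used by several tests: perfect cues, no noise.
separable_config <- function(n = 60, seed = 3) {
  generator_config(n_records = n, cue_strength = 1,
                   noise = noise_config(0, 0), seed = seed)
}

# Tiny CNN architecture for fast functional tests.
tiny_cnn_spec <- function(region_sizes = 1, maps = 8, dim = 16, ...) {
  cnn_spec(region_sizes = region_sizes, n_feature_maps = maps,
           embedding = embedding_spec("random", dim = dim, seed = 4), ...)
}

nbm_cv_mmae <- function(tok, k = 5, seed = 1) {
  crossval_model(tok, "nbm", k = k, seed = seed)$mmae
}

# Per-class MAEs printed for the held-out test set of the source study
# (columns: C4.5, SVM, NBM, m-CNN, c-m CNN, m-CNN', c-m CNN').
published_test_maes <- function() {
  list(
    c4.5      = c(0.968, 0.430, 0.630, 0.925),
    svm       = c(0.645, 0.360, 0.761, 0.698),
    nbm       = c(0.645, 0.244, 0.652, 0.792),
    m_cnn     = c(0.871, 0.384, 0.413, 0.642),
    cm_cnn    = c(0.742, 0.407, 0.522, 0.660),
    m_cnn_d   = c(0.677, 0.337, 0.500, 0.642),
    cm_cnn_d  = c(0.677, 0.419, 0.478, 0.623)
  )
}

published_overall_row <- function() {
  c(c4.5 = 0.738, svm = 0.616, nbm = 0.583, m_cnn = 0.577,
    cm_cnn = 0.583, m_cnn_d = 0.539, cm_cnn_d = 0.549)
}
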
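test_that("vocabulary counts distinct tokens plus one reserved index", {
  words <- sprintf("w%02d", 1:50)
  tok <- tok_from_texts(paste(words, collapse = " "))
  v <- build_vocabulary(tok, min_count = 1)
  expect_identical(v$size, 51L)
  expect_identical(v$tokens[1], "<pad>")

  # hapaxes drop at min_count = 2
  tok2 <- tok_from_texts(c("alpha alpha beta", "alpha gamma"))
  v2 <- build_vocabulary(tok2, min_count = 2)
  expect_identical(sort(v2$tokens), sort(c("<pad>", "alpha")))

  # deterministic assignment: frequency desc then lexicographic
  v3a <- build_vocabulary(tok2)
  v3b <- build_vocabulary(tok2)
  expect_identical(v3a, v3b)
  expect_identical(v3a$tokens, c("<pad>", "alpha", "beta", "gamma"))

  empty <- tok_from_texts("")
  expect_error(build_vocabulary(empty), "empty")
})

test_that("encoding pads, truncates and maps unknown tokens to the reserved index", {
  tok <- tok_from_texts("a b c d e f")
  v <- build_vocabulary(tok)
  enc <- encode_corpus(tok, v, max_length = 8)
  expect_identical(dim(enc$sequences), c(1L, 8L))
  expect_identical(sum(enc$sequences[1, ] == 1L), 2L)  # two padding cells
  expect_identical(enc$lengths, 6L)

  tok10 <- tok_from_texts("a b c d e f g h i j")
  enc10 <- encode_corpus(tok10, build_vocabulary(tok10), max_length = 8)
  expect_identical(enc10$lengths, 8L)
  # prefix kept: first token of text is at position 1
  first_tok <- tok10$records[[1]]$tokens[1]
  expect_identical(enc10$vocabulary$tokens[enc10$sequences[1, 1]], first_tok)

  unk <- tok_from_texts("a b zzz")
  encu <- encode_corpus(unk, v, max_length = 4)
  expect_identical(encu$sequences[1, 3], 1L)

  expect_error(encode_corpus(tok, v, max_length = 0), "max_length")

  # encode/decode identity on in-vocabulary tokens
  dec <- v$tokens[enc$sequences[1, 1:6]]
  expect_identical(dec, tok$records[[1]]$tokens)
})

test_that("embedding regimes honour their contracts", {
  tok <- tok_from_texts("red green blue white")
  v <- build_vocabulary(tok)  # V = 5

  one_hot <- make_embedding_matrix(embedding_spec("one_hot_fixed"), v)
  expect_identical(unname(one_hot[, ]), diag(1, 5, 5)[, ])
  expect_false(attr(one_hot, "trainable"))
  expect_error(embedding_spec("one_hot_fixed", trainable = TRUE), "frozen")

  unif <- make_embedding_matrix(embedding_spec("random", dim = 10, seed = 2), v)
  expect_identical(dim(unif), c(5L, 10L))
  expect_true(all(abs(unif) <= 0.05))
  unif2 <- make_embedding_matrix(embedding_spec("random", dim = 10, seed = 2), v)
  expect_identical(unif, unif2)  # bit-reproducible

  glo <- make_embedding_matrix(
    embedding_spec("random", dim = 300, init = "glorot_uniform", seed = 2), v)
  expect_true(all(abs(glo) <= sqrt(6 / (5 + 300))))
})

test_that("pretrained embeddings copy known rows and randomise OOV and forced-OOV rows", {
  tok <- tok_from_texts("red green blue Yes")
  v <- build_vocabulary(tok)
  pre <- matrix(seq_len(4 * 3) / 10, nrow = 4,
                dimnames = list(c("red", "green", "Yes", "unrelated"), NULL))
  path <- withr::local_tempfile(fileext = ".vec")
  write_word2vec(pre, path)
  expect_equal(unname(read_word2vec(path)), unname(pre), tolerance = 1e-6)

  spec <- embedding_spec("pretrained", dim = 3, pretrained_path = path, seed = 9)
  emb <- make_embedding_matrix(spec, v)
  expect_equal(emb[v$index[["red"]], ], pre["red", ], tolerance = 1e-6,
               ignore_attr = TRUE)
  # "blue" is absent from the file: seeded-random row, within init bounds
  blue <- emb[v$index[["blue"]], ]
  expect_true(all(abs(blue) <= 0.05))
  emb2 <- make_embedding_matrix(spec, v)
  expect_identical(emb, emb2)

  # forced-OOV words lose their pretrained rows even though present
  spec_f <- embedding_spec("pretrained", dim = 3, pretrained_path = path,
                           forced_oov = c("Yes", "No", "None", "Uncertain"),
                           seed = 9)
  emb_f <- make_embedding_matrix(spec_f, v)
  expect_false(isTRUE(all.equal(emb_f[v$index[["Yes"]], ], pre["Yes", ],
                                check.attributes = FALSE)))
  expect_true(all(abs(emb_f[v$index[["Yes"]], ]) <= 0.05))

  expect_error(
    make_embedding_matrix(
      embedding_spec("pretrained", dim = 5, pretrained_path = path), v),
    "mismatch")
  expect_error(read_word2vec(file.path(tempdir(), "absent.vec")), "cannot read")
  expect_error(embedding_spec("pretrained"), "pretrained_path")
})

test_that("one-hot model output is invariant to vocabulary permutation", {
  tok <- tok_from_texts(c("aa bb cc dd", "cc dd ee ff"),
                        labels = c("MILD", "SEVERE"))
  v <- build_vocabulary(tok)
  spec <- cnn_spec(region_sizes = 1, n_feature_maps = 3,
                   embedding = embedding_spec("one_hot_fixed"))
  model <- build_cnn(spec, v, seed = 6)
  enc <- encode_corpus(tok, v, max_length = 4)
  base <- predict(model, enc)

  # permute non-reserved vocabulary entries and the filter rows to match
  set.seed(17)
  perm <- c(1L, 1L + sample(v$size - 1L))
  v2 <- v
  v2$tokens[perm] <- v$tokens
  v2$index <- stats::setNames(seq_along(v2$tokens), v2$tokens)
  model2 <- model
  model2$vocabulary <- v2
  model2$regions[[1]]$w[perm, ] <- model$regions[[1]]$w
  enc2 <- encode_corpus(tok, v2, max_length = 4)
  permuted <- predict(model2, enc2)
  expect_equal(permuted[paste0("p_", severity_classes())],
               base[paste0("p_", severity_classes())], tolerance = 1e-12)
})
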
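# Independent brute-force oracles, deliberately written as plain loops.
brute_convolve <- function(word_matrix, filter_bank, bias) {
  n <- nrow(word_matrix); h <- dim(filter_bank)[1]; k <- dim(filter_bank)[3]
  out <- matrix(NA_real_, k, n - h + 1)
  for (j in seq_len(k)) {
    for (i in seq_len(n - h + 1)) {
      s <- sum(filter_bank[, , j] * word_matrix[i:(i + h - 1), , drop = FALSE]) +
        bias[j]
      out[j, i] <- max(s, 0)
    }
  }
  out
}

brute_chunk_max <- function(map, l) {
  m <- length(map)
  base <- m %/% l; rem <- m %% l
  out <- numeric(l); pos <- 0L
  for (j in seq_len(l)) {
    size <- base + (j <= rem)  # remainder goes to the earliest chunks
    out[j] <- max(map[(pos + 1L):(pos + size)])
    pos <- pos + size
  }
  out
}

test_that("convolution obeys the n - h + 1 length law and matches brute force", {
  set.seed(5)
  wm <- matrix(rnorm(10 * 3), 10, 3)
  fb <- array(rnorm(3 * 3 * 4), dim = c(3, 3, 4))
  maps <- convolve(wm, fb, bias = rnorm(4))
  expect_identical(ncol(maps), 10L - 3L + 1L)

  # zero filters and bias give all-zero maps
  expect_true(all(convolve(wm, array(0, dim = c(3, 3, 2)), c(0, 0)) == 0))

  # hand-checkable case plus random cases against the loop oracle
  wm4 <- matrix(c(1, 0, -1, 2, 0.5, 1, -2, 0), nrow = 4, byrow = TRUE)
  fb4 <- array(c(1, 0, 0, 1, -1, 1, 0.5, 0), dim = c(2, 2, 2))
  b4 <- c(0.1, -0.2)
  expect_equal(convolve(wm4, fb4, b4), brute_convolve(wm4, fb4, b4),
               tolerance = 1e-12)
  for (case in 1:20) {
    n <- sample(3:12, 1); d <- sample(1:4, 1)
    h <- sample(seq_len(n), 1); k <- sample(1:5, 1)
    wm <- matrix(rnorm(n * d), n, d)
    fb <- array(rnorm(h * d * k), dim = c(h, d, k))
    b <- rnorm(k)
    got <- convolve(wm, fb, b)
    expect_identical(dim(got), c(k, n - h + 1L))
    expect_equal(got, brute_convolve(wm, fb, b), tolerance = 1e-10)
  }
  expect_error(convolve(matrix(0, 2, 3), array(0, dim = c(5, 3, 1)), 0),
               "too short")
})

test_that("pooling operators take exact segment maxima", {
  expect_identical(one_max_pool(c(0.2, 1.7, 0.0)), 1.7)
  expect_identical(one_max_pool(c(0, 0, 0)), 0)
  expect_error(one_max_pool(numeric(0)), "empty")

  expect_identical(chunk_max_pool(c(1, 5, 2, 0, 3, 4), 3), c(5, 2, 4))
  expect_identical(chunk_sizes(7, 3), c(3L, 2L, 2L))
  expect_error(chunk_max_pool(1:2, 3), "shorter")

  set.seed(8)
  for (case in 1:200) {
    m <- sample(1:40, 1); l <- sample(seq_len(m), 1)
    map <- round(rnorm(m), 3)
    got <- chunk_max_pool(map, l)
    expect_equal(got, brute_chunk_max(map, l), tolerance = 0)
    expect_identical(chunk_max_pool(map, 1L), one_max_pool(map))
    # singleton chunks reproduce the map itself
    expect_identical(chunk_max_pool(map, m), map)
  }
})

test_that("pooled-vector length follows maps x chunks summed over regions", {
  expect_identical(pooled_length(cnn_spec(region_sizes = 2,
                                          n_feature_maps = 100)), 100L)
  expect_identical(pooled_length(cnn_spec(region_sizes = c(1, 2, 5),
                                          n_feature_maps = 100)), 300L)
  expect_identical(
    pooled_length(cnn_spec(region_sizes = 5, n_feature_maps = 100,
                           pooling = "chunk_max", chunk_count = 10)), 1000L)

  # the law holds for the vector an actual forward pass produces
  tok <- tok_from_texts(c("a b c d e f g h i j k l m n o p"), "MILD")
  v <- build_vocabulary(tok)
  enc <- encode_corpus(tok, v, max_length = 16)
  set.seed(3)
  for (case in 1:10) {
    rs <- sort(sample(1:4, sample(1:3, 1)))
    pool <- sample(c("one_max", "chunk_max"), 1)
    l <- if (pool == "chunk_max") sample(1:3, 1) else 1
    spec <- cnn_spec(region_sizes = rs, n_feature_maps = sample(2:6, 1),
                     pooling = pool, chunk_count = l,
                     embedding = embedding_spec("random", dim = 5, seed = case))
    model <- build_cnn(spec, v, seed = case)
    fwd <- sevcnn:::cnn_forward(model, enc$sequences[1, ], enc$lengths[1])
    expect_identical(length(fwd$pooled), pooled_length(spec))
  }
})

test_that("softmax output is a proper simplex and untrained zero weights give uniform probabilities", {
  tok <- tok_from_texts(c("a b c d", "b c d e"), c("MILD", "SEVERE"))
  v <- build_vocabulary(tok)
  enc <- encode_corpus(tok, v, max_length = 4)
  model <- build_cnn(tiny_cnn_spec(), v, seed = 1)
  model$u[] <- 0; model$u0[] <- 0
  p <- predict(model, enc)
  probs <- as.matrix(p[paste0("p_", severity_classes())])
  expect_equal(unname(probs), matrix(0.25, 2, 4), tolerance = 1e-12)

  model2 <- build_cnn(tiny_cnn_spec(), v, seed = 2)
  p2 <- as.matrix(predict(model2, enc)[paste0("p_", severity_classes())])
  expect_equal(unname(rowSums(p2)), c(1, 1), tolerance = 1e-9)
})

test_that("a hand-set forward pass reproduces the manual computation", {
  # 1 record, 3 tokens, d = 2, h = 2, two filters, one-max pooling
  tok <- tok_from_texts("aa bb cc", "MODERATE")
  v <- build_vocabulary(tok)  # <pad>, aa, bb, cc
  spec <- cnn_spec(region_sizes = 2, n_feature_maps = 2,
                   embedding = embedding_spec("random", dim = 2, seed = 1))
  model <- build_cnn(spec, v, seed = 1)
  emb <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))  # pad, aa, bb, cc
  model$embedding <- emb
  # filter j weights, layout: word 1 dims then word 2 dims
  model$regions[[1]]$w <- cbind(c(1, 0, 0, 1), c(-1, 0, 0, -1))
  model$regions[[1]]$b <- c(0, 0.5)
  model$u <- rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 0))
  model$u0 <- rep(0, 4)
  # windows: (aa,bb) -> f1: 1*1 + 1*1? no: aa=(1,0), bb=(0,1): f1 = 1*1+0*0+0*0+1*1 = 2
  #          (bb,cc) -> f1 = 1*0+0*1+0*1+1*1 = 1 ; pooled f1 = max(2,1) = 2
  # f2: -(those) + 0.5 -> ReLU(-1.5)=0, ReLU(-0.5)=0 ; pooled f2 = 0
  # logits = (0, 2, 0, 4) -> argmax SEVERE
  enc <- encode_corpus(tok, v, max_length = 3)
  fwd <- sevcnn:::cnn_forward(model, enc$sequences[1, ], enc$lengths[1])
  expect_equal(fwd$pooled, c(2, 0), tolerance = 1e-12)
  p <- predict(model, enc)
  expect_identical(p$predicted, "SEVERE")
  expect_equal(p$p_SEVERE, exp(4) / sum(exp(c(0, 2, 0, 4))), tolerance = 1e-9)
})

test_that("prediction is deterministic with dropout configured", {
  tok <- tok_from_texts(c("a b c d e", "c d e f g"), c("MILD", "SEVERE"))
  v <- build_vocabulary(tok)
  enc <- encode_corpus(tok, v)
  spec <- tiny_cnn_spec(dropout_rate = 0.5)
  model <- train_cnn(build_cnn(spec, v, seed = 1), enc,
                     config = train_config(epochs = 3, seed = 1))
  expect_identical(predict(model, enc), predict(model, enc))
})

test_that("training at zero learning rate leaves every weight unchanged", {
  co <- generate_corpus(separable_config(n = 12, seed = 5))
  tok <- normalise_questions(preprocess_corpus(co))
  v <- build_vocabulary(tok)
  enc <- encode_corpus(tok, v)
  model <- build_cnn(tiny_cnn_spec(), v, seed = 2)
  cfg <- train_config(learning_rate = 1, epochs = 2, optimiser = "sgd", seed = 1)
  cfg$learning_rate <- 0  # constructor enforces > 0; the invariant needs 0
  trained <- train_cnn(model, enc, config = cfg)
  expect_identical(trained$u, model$u)
  expect_identical(trained$regions, model$regions)
  expect_identical(trained$embedding, model$embedding)
})

test_that("training hyperparameters are validated", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(cnn_spec(dropout_rate = 1), "dropout_rate")
})

test_that("a basic CNN fits a perfectly cued corpus", {
  co <- generate_corpus(separable_config(n = 60, seed = 3))
  tok <- normalise_questions(preprocess_corpus(co))
  v <- build_vocabulary(tok)
  enc <- encode_corpus(tok, v)
  spec <- cnn_spec(region_sizes = 1, n_feature_maps = 100,
                   embedding = embedding_spec("random", dim = 200, seed = 1))
  model <- train_cnn(build_cnn(spec, v, seed = 1), enc,
                     config = train_config(0.001, epochs = 25, seed = 1))
  p <- predict(model, enc)
  lp <- labeled_predictions(p$record_id, enc$labels, p$predicted)
  expect_lt(mmae(lp), 0.15)
  # the loss trace is a finite, broadly decreasing record of training
  expect_true(all(is.finite(model$loss_trace)))
  expect_lt(model$loss_trace[25], model$loss_trace[1])
})

test_that("checkpoints roundtrip through JSON", {
  tok <- tok_from_texts(c("a b c d e", "c d e f g"), c("MILD", "SEVERE"))
  v <- build_vocabulary(tok)
  enc <- encode_corpus(tok, v)
  model <- train_cnn(build_cnn(tiny_cnn_spec(), v, seed = 1), enc,
                     config = train_config(epochs = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn_checkpoint(model, path)
  back <- read_cnn_checkpoint(path)
  expect_equal(predict(back, enc), predict(model, enc), tolerance = 1e-12)
})
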
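#' CNN architecture specification
#'
#' Describes one member of the document-CNN family: a single-region 1-max
#' model, a parallel model (several region sizes whose pooled outputs are
#' concatenated), or a chunk-max pooling model (each feature map split into
#' `chunk_count` contiguous chunks, max-pooled per chunk, preserving coarse
#' positional order). The pooled vector has length
#' sum over regions of `n_feature_maps * (1 or chunk_count)`; dropout (if
#' any) is applied to it before the fully connected 4-way softmax.
#'
#' @param region_sizes Integer vector of filter heights h (words per window).
#' @param n_feature_maps Feature maps (filters) per region size.
#' @param pooling "one_max" or "chunk_max".
#' @param chunk_count Number of chunks l (chunk_max only).
#' @param dropout_rate Dropout on the pooled vector, in \[0, 1).
#' @param embedding An [embedding_spec()].
#' @return A `cnn_spec`.
#' @export
cnn_spec <- function(region_sizes = 5, n_feature_maps = 100,
                     pooling = c("one_max", "chunk_max"), chunk_count = 1,
                     dropout_rate = 0, embedding = embedding_spec()) {
  pooling <- match.arg(pooling)
  region_sizes <- vapply(region_sizes, assert_count, integer(1),
                         name = "region_sizes")
  n_feature_maps <- assert_count(n_feature_maps, "n_feature_maps")
  chunk_count <- assert_count(chunk_count, "chunk_count")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(embedding, "embedding_spec"))
  structure(
    list(region_sizes = region_sizes, n_feature_maps = n_feature_maps,
         pooling = pooling,
         chunk_count = if (pooling == "chunk_max") chunk_count else 1L,
         dropout_rate = dropout_rate, embedding = embedding,
         n_classes = 4L),
    class = "cnn_spec"
  )
}

#' Training hyperparameters
#'
#' @param learning_rate Step size (the source experiments use 0.001 for
#'   max-pooling models and 0.1 for chunk-max pooling models).
#' @param epochs Number of passes over the training set (default 150).
#' @param batch_size Mini-batch size (unreported in the source; default 32).
#' @param seed Seed governing shuffling, dropout and weight initialisation.
#' @param optimiser "adam" (default) or "sgd". The source does not name its
#'   optimiser; see the methods vignette for why Adam is the default at
#'   these learning rates.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 150, batch_size = 32,
                         seed = 1, optimiser = c("adam", "sgd")) {
  optimiser <- match.arg(optimiser)
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be > 0", call. = FALSE)
  }
  epochs <- assert_count(epochs, "epochs")
  batch_size <- assert_count(batch_size, "batch_size")
  structure(
    list(learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, seed = as.integer(seed),
         optimiser = optimiser),
    class = "train_config"
  )
}

#' Convolution of a word matrix with a filter bank
#'
#' Each filter spans `h` consecutive word rows and the full embedding width;
#' position i yields `ReLU(sum(filter * word_matrix[i:(i+h-1), ]) + bias)`,
#' producing a feature map of length exactly n - h + 1.
#'
#' @param word_matrix n x d numeric matrix (one row per word).
#' @param filter_bank h x d x k array (k filters).
#' @param bias Numeric vector of length k.
#' @return k x (n - h + 1) matrix of feature maps (row = filter).
#' @export
convolve <- function(word_matrix, filter_bank, bias) {
  stopifnot(is.matrix(word_matrix), length(dim(filter_bank)) == 3L)
  n <- nrow(word_matrix); d <- ncol(word_matrix)
  h <- dim(filter_bank)[1]; k <- dim(filter_bank)[3]
  if (dim(filter_bank)[2] != d) stop("filter width must equal embedding dim",
                                     call. = FALSE)
  if (length(bias) != k) stop("bias length must equal filter count", call. = FALSE)
  if (n < h) stop(sprintf("input too short for region size: n=%d < h=%d", n, h),
                  call. = FALSE)
  w <- flatten_filters(filter_bank)           # (h*d) x k
  x <- window_matrix(word_matrix, h)          # (n-h+1) x (h*d)
  pre <- sweep(x %*% w, 2L, bias, `+`)
  t(pmax(pre, 0))
}

# Row i of the result is the window x_{i:i+h-1} flattened word-major
# (word i's d values, then word i+1's, ...).
window_matrix <- function(word_matrix, h) {
  n <- nrow(word_matrix)
  m <- n - h + 1L
  if (h == 1L) return(word_matrix)
  do.call(cbind, lapply(0:(h - 1L), function(j) {
    word_matrix[(1L + j):(m + j), , drop = FALSE]
  }))
}

flatten_filters <- function(filter_bank) {
  k <- dim(filter_bank)[3]
  vapply(seq_len(k), function(j) as.vector(t(filter_bank[, , j])),
         numeric(dim(filter_bank)[1] * dim(filter_bank)[2]))
}

#' 1-max pooling of a feature map
#'
#' @param feature_map Non-empty numeric vector.
#' @return Its maximum activation.
#' @export
one_max_pool <- function(feature_map) {
  if (length(feature_map) == 0L) stop("empty feature map", call. = FALSE)
  max(feature_map)
}

#' Chunk sizes for chunk-max pooling
#'
#' Splits a length-m map into l contiguous chunks; the remainder is
#' distributed to the earliest chunks, so sizes are ceiling(m/l) then
#' floor(m/l).
#'
#' @param m Feature-map length.
#' @param l Chunk count (must satisfy l <= m).
#' @return Integer vector of l chunk sizes summing to m.
#' @export
chunk_sizes <- function(m, l) {
  if (m < l) stop(sprintf("feature map shorter than chunk count: m=%d < l=%d",
                          m, l), call. = FALSE)
  sizes <- rep(m %/% l, l)
  r <- m %% l
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  as.integer(sizes)
}

#' Chunk-max pooling of a feature map
#'
#' @param feature_map Numeric vector of length m >= l.
#' @param l Chunk count.
#' @return Numeric vector of length l: the max of each chunk, in order.
#' @export
chunk_max_pool <- function(feature_map, l) {
  l <- assert_count(l, "l")
  sizes <- chunk_sizes(length(feature_map), l)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  vapply(seq_len(l), function(j) max(feature_map[starts[j]:ends[j]]),
         numeric(1))
}

#' Pooled feature-vector length of an architecture
#' @param spec A [cnn_spec()].
#' @return Integer: sum over regions of maps x chunks.
#' @export
pooled_length <- function(spec) {
  per_region <- spec$n_feature_maps *
    (if (spec$pooling == "chunk_max") spec$chunk_count else 1L)
  length(spec$region_sizes) * per_region
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nrow = nr)
}

#' Build (initialise) a CNN model
#'
#' Realises the embedding matrix for `vocabulary` per the spec's embedding
#' regime and Glorot-initialises convolution filters and the softmax layer.
#'
#' @param spec A [cnn_spec()].
#' @param vocabulary From [build_vocabulary()].
#' @param seed Seed for weight initialisation (embedding rows follow the
#'   embedding spec's own seed).
#' @return A `cnn_model` (untrained).
#' @export
build_cnn <- function(spec, vocabulary, seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(vocabulary, "vocabulary"))
  emb <- make_embedding_matrix(spec$embedding, vocabulary)
  d <- ncol(emb)
  p <- pooled_length(spec)
  model <- with_seed(seed, {
    regions <- lapply(spec$region_sizes, function(h) {
      list(h = as.integer(h),
           w = glorot(h * d, spec$n_feature_maps),
           b = numeric(spec$n_feature_maps))
    })
    list(spec = spec,
         vocabulary = vocabulary,
         embedding = unclass_matrix(emb),
         emb_trainable = isTRUE(attr(emb, "trainable")),
         regions = regions,
         u = glorot(spec$n_classes, p),
         u0 = numeric(spec$n_classes),
         pooled_length = p,
         trained = FALSE,
         loss_trace = numeric(0))
  })
  class(model) <- "cnn_model"
  model
}

unclass_matrix <- function(m) {
  attr(m, "trainable") <- NULL
  attr(m, "mode") <- NULL
  m
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Forward pass for one record. idx: padded index row; len: true token count.
# Pure-padding windows are excluded from pooling; with right-padding that
# means windows 1..min(len, max_length - h + 1).
cnn_forward <- function(model, idx, len, train = FALSE, drop_mask = NULL) {
  spec <- model$spec
  l <- if (spec$pooling == "chunk_max") spec$chunk_count else 1L
  k <- spec$n_feature_maps
  caches <- vector("list", length(model$regions))
  pooled <- numeric(0)
  for (ri in seq_along(model$regions)) {
    reg <- model$regions[[ri]]
    h <- reg$h
    n_use <- min(length(idx), len + h - 1L)
    rows <- idx[seq_len(n_use)]
    emat <- model$embedding[rows, , drop = FALSE]
    x <- window_matrix(emat, h)
    m <- nrow(x)
    if (m < l) {
      stop(sprintf(
        "record too short for chunk-max pooling: %d valid windows < l=%d (region %d)",
        m, l, h), call. = FALSE)
    }
    pre <- sweep(x %*% reg$w, 2L, reg$b, `+`)
    act <- pmax(pre, 0)
    sizes <- chunk_sizes(m, l)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    pos <- matrix(0L, nrow = l, ncol = k)
    vals <- matrix(0, nrow = l, ncol = k)
    for (cj in seq_len(l)) {
      sub <- act[starts[cj]:ends[cj], , drop = FALSE]
      p_in <- max.col(t(sub), ties.method = "first")
      pos[cj, ] <- p_in + starts[cj] - 1L
      vals[cj, ] <- sub[cbind(p_in, seq_len(k))]
    }
    # filter-major: each filter's l chunk maxima are contiguous
    pooled_r <- as.vector(vals)        # column-major: filter j -> chunks 1..l
    caches[[ri]] <- list(x = x, rows = rows, pos = pos, vals = vals, m = m)
    pooled <- c(pooled, pooled_r)
  }
  if (train && spec$dropout_rate > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- stats::runif(length(pooled)) >= spec$dropout_rate
    }
    pooled_d <- pooled * drop_mask / (1 - spec$dropout_rate)
  } else {
    drop_mask <- NULL
    pooled_d <- pooled
  }
  logits <- drop(model$u %*% pooled_d) + model$u0
  probs <- softmax(logits)
  list(probs = probs, pooled = pooled, pooled_d = pooled_d,
       drop_mask = drop_mask, caches = caches)
}

# Backward pass for one record; returns gradients in model layout.
cnn_backward <- function(model, fwd, y_idx) {
  spec <- model$spec
  l <- if (spec$pooling == "chunk_max") spec$chunk_count else 1L
  k <- spec$n_feature_maps
  dlogits <- fwd$probs
  dlogits[y_idx] <- dlogits[y_idx] - 1
  du <- tcrossprod(dlogits, fwd$pooled_d)
  du0 <- dlogits
  dpool <- drop(crossprod(model$u, dlogits))
  if (!is.null(fwd$drop_mask)) {
    dpool <- dpool * fwd$drop_mask / (1 - spec$dropout_rate)
  }
  d_regions <- vector("list", length(model$regions))
  demb <- if (model$emb_trainable) list() else NULL
  off <- 0L
  for (ri in seq_along(model$regions)) {
    cache <- fwd$caches[[ri]]
    reg <- model$regions[[ri]]
    g <- matrix(dpool[off + seq_len(k * l)], nrow = l, ncol = k)
    off <- off + k * l
    g <- g * (cache$vals > 0)           # ReLU gate at the max position
    # scatter into an (m x k) gradient, nonzero only at argmax positions
    nz <- which(g != 0, arr.ind = TRUE)
    dw <- matrix(0, nrow = nrow(reg$w), ncol = k)
    db <- numeric(k)
    dx_rows <- NULL
    if (nrow(nz)) {
      pos_used <- cache$pos[nz]
      upos <- sort(unique(pos_used))
      s <- matrix(0, nrow = length(upos), ncol = k)
      s[cbind(match(pos_used, upos), nz[, 2])] <- g[nz]
      dw <- crossprod(cache$x[upos, , drop = FALSE], s)
      db <- colSums(s)
      if (model$emb_trainable) {
        dx <- s %*% t(reg$w)                # |upos| x (h*d)
        dx_rows <- list(upos = upos, dx = dx)
      }
    }
    d_regions[[ri]] <- list(w = dw, b = db)
    if (model$emb_trainable && !is.null(dx_rows)) {
      d <- ncol(model$embedding)
      h <- reg$h
      for (j in 0:(h - 1L)) {
        block <- dx_rows$dx[, j * d + seq_len(d), drop = FALSE]
        tok_rows <- cache$rows[dx_rows$upos + j]
        agg <- rowsum(block, tok_rows)
        demb[[length(demb) + 1L]] <-
          list(rows = as.integer(rownames(agg)), grad = agg)
      }
    }
  }
  list(du = du, du0 = du0, d_regions = d_regions, demb = demb)
}

adam_state <- function(dim) list(m = array(0, dim), v = array(0, dim))

adam_update <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train a CNN model
#'
#' Mini-batch training on the 4-class cross-entropy loss. Static embedding
#' regimes leave the embedding matrix bit-identical; dynamic regimes update
#' it via backpropagation. Fully seeded: shuffling and dropout flow from the
#' training seed.
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param encoded An `encoded_corpus` (must use the model's vocabulary).
#' @param labels Gold severity labels for every record (defaults to the
#'   labels carried by `encoded`).
#' @param config A [train_config()].
#' @return The trained `cnn_model` with `loss_trace` (mean cross-entropy per
#'   epoch).
#' @export
train_cnn <- function(model, encoded, labels = encoded$labels,
                      config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(encoded, "encoded_corpus"))
  if (!identical(model$vocabulary$tokens, encoded$vocabulary$tokens)) {
    stop("encoded corpus was built with a different vocabulary", call. = FALSE)
  }
  n <- nrow(encoded$sequences)
  if (length(labels) != n || anyNA(labels)) {
    stop("labels required for every training record", call. = FALSE)
  }
  y <- severity_score(labels)
  lr <- config$learning_rate
  use_adam <- config$optimiser == "adam"

  st <- NULL
  if (use_adam) {
    st <- list(u = adam_state(dim(model$u)), u0 = adam_state(length(model$u0)),
               regions = lapply(model$regions, function(r) {
                 list(w = adam_state(dim(r$w)), b = adam_state(length(r$b)))
               }),
               emb = if (model$emb_trainable) adam_state(dim(model$embedding)))
  }
  t_step <- 0L
  losses <- numeric(config$epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        batch <- perm[b0:min(b0 + config$batch_size - 1L, n)]
        bs <- length(batch)
        gu <- matrix(0, nrow(model$u), ncol(model$u)); gu0 <- numeric(4)
        greg <- lapply(model$regions, function(r) {
          list(w = matrix(0, nrow(r$w), ncol(r$w)), b = numeric(length(r$b)))
        })
        gemb <- if (model$emb_trainable) {
          matrix(0, nrow(model$embedding), ncol(model$embedding))
        }
        for (i in batch) {
          fwd <- cnn_forward(model, encoded$sequences[i, ], encoded$lengths[i],
                             train = TRUE)
          ep_loss <- ep_loss - log(max(fwd$probs[y[i]], 1e-12))
          bwd <- cnn_backward(model, fwd, y[i])
          gu <- gu + bwd$du; gu0 <- gu0 + bwd$du0
          for (ri in seq_along(greg)) {
            greg[[ri]]$w <- greg[[ri]]$w + bwd$d_regions[[ri]]$w
            greg[[ri]]$b <- greg[[ri]]$b + bwd$d_regions[[ri]]$b
          }
          if (model$emb_trainable && length(bwd$demb)) {
            for (dmb in bwd$demb) {
              gemb[dmb$rows, ] <- gemb[dmb$rows, ] + dmb$grad
            }
          }
        }
        t_step <- t_step + 1L
        if (use_adam) {
          up <- adam_update(model$u, gu / bs, st$u, lr, t_step)
          model$u <- up$par; st$u <- up$state
          up <- adam_update(model$u0, gu0 / bs, st$u0, lr, t_step)
          model$u0 <- up$par; st$u0 <- up$state
          for (ri in seq_along(model$regions)) {
            up <- adam_update(model$regions[[ri]]$w, greg[[ri]]$w / bs,
                              st$regions[[ri]]$w, lr, t_step)
            model$regions[[ri]]$w <- up$par; st$regions[[ri]]$w <- up$state
            up <- adam_update(model$regions[[ri]]$b, greg[[ri]]$b / bs,
                              st$regions[[ri]]$b, lr, t_step)
            model$regions[[ri]]$b <- up$par; st$regions[[ri]]$b <- up$state
          }
          if (model$emb_trainable) {
            up <- adam_update(model$embedding, gemb / bs, st$emb, lr, t_step)
            model$embedding <- up$par; st$emb <- up$state
          }
        } else {
          model$u <- model$u - lr * gu / bs
          model$u0 <- model$u0 - lr * gu0 / bs
          for (ri in seq_along(model$regions)) {
            model$regions[[ri]]$w <- model$regions[[ri]]$w - lr * greg[[ri]]$w / bs
            model$regions[[ri]]$b <- model$regions[[ri]]$b - lr * greg[[ri]]$b / bs
          }
          if (model$emb_trainable) {
            model$embedding <- model$embedding - lr * gemb / bs
          }
        }
      }
      losses[epoch] <- ep_loss / n
      if (!is.finite(losses[epoch])) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (learning rate %g)",
          epoch, lr), call. = FALSE)
      }
    }
  })
  model$trained <- TRUE
  model$loss_trace <- losses
  model
}

#' Predict class probabilities for encoded records
#'
#' Deterministic given fixed weights (dropout is inference-off). Ties in the
#' argmax resolve to the lower severity.
#'
#' @param object A `cnn_model`.
#' @param encoded An `encoded_corpus`.
#' @param ... Unused.
#' @return Data frame: record_id, predicted, p_ABSENT .. p_SEVERE.
#' @export
predict.cnn_model <- function(object, encoded, ...) {
  stopifnot(inherits(encoded, "encoded_corpus"))
  n <- nrow(encoded$sequences)
  probs <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, paste0("p_", severity_classes())))
  for (i in seq_len(n)) {
    fwd <- cnn_forward(object, encoded$sequences[i, ], encoded$lengths[i],
                       train = FALSE)
    probs[i, ] <- fwd$probs
  }
  pred <- severity_classes()[apply(probs, 1L, which.max)]
  cbind(data.frame(record_id = encoded$record_ids, predicted = pred,
                   stringsAsFactors = FALSE),
        as.data.frame(probs))
}

#' Save / load a CNN model checkpoint (JSON)
#'
#' Architecture spec plus weight arrays, in plain JSON.
#'
#' @param model A `cnn_model`.
#' @param path Checkpoint path.
#' @return `write_cnn_checkpoint` invisibly returns `path`;
#'   `read_cnn_checkpoint` returns the restored `cnn_model`.
#' @export
write_cnn_checkpoint <- function(model, path) {
  payload <- list(
    spec = unclass_spec(model$spec),
    vocabulary_tokens = model$vocabulary$tokens,
    vocabulary_lowercase = model$vocabulary$lowercase,
    embedding = model$embedding,
    emb_trainable = model$emb_trainable,
    regions = lapply(model$regions, function(r) list(h = r$h, w = r$w, b = r$b)),
    u = model$u, u0 = model$u0, trained = model$trained,
    loss_trace = model$loss_trace
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

unclass_spec <- function(spec) {
  out <- unclass(spec)
  out$embedding <- unclass(out$embedding)
  out
}

#' @rdname write_cnn_checkpoint
#' @export
read_cnn_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- structure(
    list(tokens = p$vocabulary_tokens,
         index = stats::setNames(seq_along(p$vocabulary_tokens),
                                 p$vocabulary_tokens),
         size = length(p$vocabulary_tokens),
         lowercase = isTRUE(p$vocabulary_lowercase)),
    class = "vocabulary"
  )
  es <- p$spec$embedding
  spec <- cnn_spec(
    region_sizes = p$spec$region_sizes,
    n_feature_maps = p$spec$n_feature_maps,
    pooling = p$spec$pooling,
    chunk_count = max(1L, p$spec$chunk_count),
    dropout_rate = p$spec$dropout_rate,
    embedding = embedding_spec(
      mode = es$mode, dim = es$dim,
      trainable = if (es$mode == "one_hot_fixed") NULL else es$trainable,
      init = es$init,
      pretrained_path = es$pretrained_path,
      forced_oov = es$forced_oov %||% character(0),
      seed = es$seed
    )
  )
  model <- list(
    spec = spec, vocabulary = vocab,
    embedding = as.matrix(p$embedding),
    emb_trainable = isTRUE(p$emb_trainable),
    regions = lapply(seq_len(nrow_or_len(p$regions)), function(i) {
      r <- if (is.data.frame(p$regions)) {
        list(h = p$regions$h[i], w = p$regions$w[[i]], b = p$regions$b[[i]])
      } else p$regions[[i]]
      list(h = as.integer(r$h), w = as.matrix(r$w), b = as.numeric(r$b))
    }),
    u = as.matrix(p$u), u0 = as.numeric(p$u0),
    pooled_length = NA_integer_,
    trained = isTRUE(p$trained),
    loss_trace = as.numeric(p$loss_trace)
  )
  model$pooled_length <- pooled_length(spec)
  class(model) <- "cnn_model"
  model
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Write predictions as TSV
#' @param predictions Data frame from [predict.cnn_model()] or a baseline.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
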
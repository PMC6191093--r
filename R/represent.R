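#' Build a vocabulary from a tokenized corpus
#'
#' Tokens with corpus frequency >= `min_count` are indexed deterministically
#' (frequency descending, then lexicographic). Index 1 is the reserved
#' `<pad>` entry, used both for right-padding and for out-of-vocabulary
#' tokens at encoding time; padding-only convolution windows are masked out
#' of pooling, so the shared index only ever carries OOV signal
#' mid-sequence.
#'
#' @param tok A `tokenized_corpus`.
#' @param min_count Minimum token frequency.
#' @param lowercase Lowercase tokens before counting (default off: case is
#'   meaningful to the refinement rules upstream).
#' @return A `vocabulary`: list with `tokens` (index -> token), `index`
#'   (token -> index) and `size`.
#' @export
build_vocabulary <- function(tok, min_count = 1, lowercase = FALSE) {
  stopifnot(inherits(tok, "tokenized_corpus"))
  all_tokens <- unlist(lapply(tok$records, `[[`, "tokens"), use.names = FALSE)
  if (length(all_tokens) == 0L) stop("empty corpus: no tokens", call. = FALSE)
  if (lowercase) all_tokens <- tolower(all_tokens)
  freq <- table(all_tokens)
  keep <- freq[freq >= min_count]
  ord <- order(-as.integer(keep), names(keep))
  tokens <- c("<pad>", names(keep)[ord])
  structure(
    list(tokens = tokens,
         index = stats::setNames(seq_along(tokens), tokens),
         size = length(tokens),
         lowercase = lowercase),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> V = %d (incl. reserved <pad>/<oov> index)\n", x$size))
  invisible(x)
}

pad_index <- function(vocabulary) 1L

#' Encode a tokenized corpus as padded integer sequences
#'
#' Token order is preserved (word order is part of the signal the
#' convolution consumes). Unknown tokens map to the reserved index;
#' sequences are right-padded to `max_length` with it, and longer sequences
#' keep their prefix.
#'
#' @param tok A `tokenized_corpus`.
#' @param vocabulary From [build_vocabulary()].
#' @param max_length Sequence length; default is the 95th percentile of
#'   record lengths (rounded up).
#' @return An `encoded_corpus`: `sequences` (N x max_length integer matrix),
#'   `lengths` (unpadded lengths, capped), `record_ids`, `labels`,
#'   `vocabulary`, `max_length`.
#' @export
encode_corpus <- function(tok, vocabulary, max_length = NULL) {
  stopifnot(inherits(tok, "tokenized_corpus"), inherits(vocabulary, "vocabulary"))
  lens <- vapply(tok$records, function(r) length(r$tokens), integer(1))
  if (is.null(max_length)) {
    max_length <- max(1L, as.integer(ceiling(stats::quantile(lens, 0.95, type = 1))))
  }
  if (!is.numeric(max_length) || max_length < 1) {
    stop("`max_length` must be >= 1", call. = FALSE)
  }
  max_length <- as.integer(max_length)
  n <- length(tok$records)
  seqs <- matrix(pad_index(vocabulary), nrow = n, ncol = max_length)
  for (i in seq_len(n)) {
    toks <- tok$records[[i]]$tokens
    if (vocabulary$lowercase) toks <- tolower(toks)
    if (length(toks) > max_length) toks <- toks[seq_len(max_length)]
    if (length(toks)) {
      idx <- vocabulary$index[toks]
      idx[is.na(idx)] <- pad_index(vocabulary)
      seqs[i, seq_along(idx)] <- idx
    }
  }
  structure(
    list(vocabulary = vocabulary,
         sequences = seqs,
         lengths = pmin(lens, max_length),
         max_length = max_length,
         record_ids = vapply(tok$records, `[[`, character(1), "record_id"),
         labels = tokenized_labels(tok)),
    class = "encoded_corpus"
  )
}

#' Word-representation specification
#'
#' The five regimes studied for the embedding layer: fixed one-hot vectors
#' (`one_hot_fixed`, dimension = vocabulary size, never trained),
#' randomly initialised vectors (uniform in +/-0.05 for the 200-d baseline,
#' Glorot-uniform for the 300-d variant), and pretrained word2vec vectors in
#' a static (frozen) or dynamic (fine-tuned) configuration. Words absent
#' from a pretrained file — and every word on `forced_oov`, a device for
#' breaking unwanted similarity among question/answer tokens — receive
#' seeded random vectors.
#'
#' @param mode One of "random", "one_hot_fixed", "pretrained".
#' @param dim Embedding dimension (ignored for one_hot_fixed).
#' @param trainable Fine-tune the matrix during training? Defaults: TRUE for
#'   random, FALSE forced for one_hot_fixed, TRUE (dynamic) for pretrained.
#' @param init "uniform" (+/-0.05) or "glorot_uniform" for random rows.
#' @param pretrained_path word2vec text-format file (required for
#'   pretrained mode).
#' @param forced_oov Words to treat as out-of-vocabulary even if present in
#'   the pretrained file.
#' @param seed Seed for random rows.
#' @return An `embedding_spec`.
#' @export
embedding_spec <- function(mode = c("random", "one_hot_fixed", "pretrained"),
                           dim = 200, trainable = NULL,
                           init = c("uniform", "glorot_uniform"),
                           pretrained_path = NULL,
                           forced_oov = character(0),
                           seed = 1) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  if (mode == "one_hot_fixed") {
    if (isTRUE(trainable)) {
      stop("one_hot_fixed embeddings are frozen by definition", call. = FALSE)
    }
    trainable <- FALSE
  }
  if (mode == "pretrained" && is.null(pretrained_path)) {
    stop("pretrained mode requires `pretrained_path`", call. = FALSE)
  }
  trainable <- trainable %||% TRUE
  structure(
    list(mode = mode, dim = as.integer(dim), trainable = isTRUE(trainable),
         init = init, pretrained_path = pretrained_path,
         forced_oov = forced_oov, seed = as.integer(seed)),
    class = "embedding_spec"
  )
}

#' Read word vectors in word2vec text format
#'
#' Header line "V d", then one token followed by d floats per line.
#'
#' @param path File path.
#' @return Numeric matrix with tokens as rownames.
#' @export
read_word2vec <- function(path) {
  if (!file.exists(path)) stop("cannot read word vectors: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("malformed word2vec header (expected 'V d'): ", lines[1], call. = FALSE)
  }
  v <- hdr[1]; d <- hdr[2]
  if (length(lines) - 1L < v) stop("word2vec file truncated", call. = FALSE)
  parts <- strsplit(trimws(lines[1 + seq_len(v)]), "\\s+")
  toks <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) {
    vals <- suppressWarnings(as.numeric(p[-1]))
    if (length(vals) != d || anyNA(vals)) {
      stop("malformed word2vec row for token '", p[1], "'", call. = FALSE)
    }
    vals
  }, numeric(d)))
  rownames(mat) <- toks
  mat
}

#' Write word vectors in word2vec text format
#' @param mat Numeric matrix with tokens as rownames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_word2vec <- function(mat, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(rownames(mat)[i],
                     paste(formatC(mat[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Realise an embedding matrix for a vocabulary
#'
#' @param spec An [embedding_spec()].
#' @param vocabulary From [build_vocabulary()].
#' @return A V x d numeric matrix with attributes `trainable` (logical) and
#'   `mode`; rows follow vocabulary index order. one_hot_fixed gives
#'   identity rows; pretrained copies file rows for in-vocabulary words and
#'   assigns seeded random rows to absent words, to everything on
#'   `forced_oov`, and to the reserved index.
#' @export
make_embedding_matrix <- function(spec, vocabulary) {
  stopifnot(inherits(spec, "embedding_spec"), inherits(vocabulary, "vocabulary"))
  v <- vocabulary$size
  random_rows <- function(n, d) {
    if (spec$init == "glorot_uniform") {
      lim <- sqrt(6 / (v + d))
      matrix(stats::runif(n * d, -lim, lim), nrow = n)
    } else {
      matrix(stats::runif(n * d, -0.05, 0.05), nrow = n)
    }
  }
  mat <- switch(
    spec$mode,
    one_hot_fixed = diag(1, v, v),
    random = with_seed(spec$seed, random_rows(v, spec$dim)),
    pretrained = {
      pre <- read_word2vec(spec$pretrained_path)
      d <- ncol(pre)
      if (!is.na(spec$dim) && spec$dim != d) {
        stop(sprintf("pretrained dimension mismatch: file has %d, spec wants %d",
                     d, spec$dim), call. = FALSE)
      }
      with_seed(spec$seed, {
        m <- random_rows(v, d)
        hit <- vocabulary$tokens %in% rownames(pre) &
          !(vocabulary$tokens %in% spec$forced_oov)
        hit[pad_index(vocabulary)] <- FALSE
        m[hit, ] <- pre[vocabulary$tokens[hit], , drop = FALSE]
        m
      })
    }
  )
  attr(mat, "trainable") <- spec$trainable
  attr(mat, "mode") <- spec$mode
  mat
}
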
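#' Bag-of-words feature table
#'
#' Token counts per record over the vocabulary (the reserved `<pad>` entry is
#' excluded — it is an encoding artefact, not a word).
#'
#' @param tok A `tokenized_corpus`.
#' @param vocabulary From [build_vocabulary()].
#' @return A `feature_table`: `record_ids`, `features`, integer `counts`
#'   matrix (records x features), `labels`.
#' @export
bag_of_words <- function(tok, vocabulary) {
  stopifnot(inherits(tok, "tokenized_corpus"), inherits(vocabulary, "vocabulary"))
  features <- vocabulary$tokens[-pad_index(vocabulary)]
  counts <- matrix(0L, nrow = length(tok$records), ncol = length(features),
                   dimnames = list(NULL, features))
  for (i in seq_along(tok$records)) {
    toks <- tok$records[[i]]$tokens
    if (vocabulary$lowercase) toks <- tolower(toks)
    tab <- table(toks[toks %in% features])
    if (length(tab)) counts[i, names(tab)] <- as.integer(tab)
  }
  structure(
    list(record_ids = vapply(tok$records, `[[`, character(1), "record_id"),
         features = features,
         counts = counts,
         labels = tokenized_labels(tok)),
    class = "feature_table"
  )
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

#' Information-gain ranking of bag-of-words features
#'
#' IG(feature) = H(class) - H(class | feature present/absent), in bits.
#' Features are ordered score descending, then name ascending, so the
#' ranking is deterministic. A single-class corpus yields all-zero scores.
#'
#' @param table A `feature_table`.
#' @param labels Gold labels (defaults to those in `table`; all required).
#' @return A `feature_ranking` data.frame: feature, score (>= 0).
#' @export
information_gain_rank <- function(table, labels = table$labels) {
  stopifnot(inherits(table, "feature_table"))
  if (anyNA(labels) || length(labels) != nrow(table$counts)) {
    stop("every record must be labelled", call. = FALSE)
  }
  y <- factor(labels, levels = severity_classes())
  n <- length(y)
  h_class <- entropy_bits(as.numeric(table(y)) / n)
  present <- table$counts > 0L
  scores <- vapply(seq_along(table$features), function(j) {
    pj <- present[, j]
    n1 <- sum(pj)
    if (n1 == 0L || n1 == n) return(0)
    h1 <- entropy_bits(as.numeric(table(y[pj])) / n1)
    h0 <- entropy_bits(as.numeric(table(y[!pj])) / (n - n1))
    max(0, h_class - (n1 / n) * h1 + (n1 / n - 1) * h0)
  }, numeric(1))
  out <- data.frame(feature = table$features, score = scores,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", class(out))
  out
}

select_features <- function(ranking, selection) {
  rule <- selection$rule %||% "ig_positive"
  feats <- switch(
    rule,
    ig_positive = ranking$feature[ranking$score > 0],
    top_k = utils::head(ranking$feature, selection$k %||%
                          stop("top_k selection needs `k`", call. = FALSE)),
    threshold = ranking$feature[ranking$score >= (selection$threshold %||% 0)],
    none = ranking$feature,
    stop("unknown selection rule: ", rule, call. = FALSE)
  )
  if (length(feats) == 0L) {
    stop("feature selection kept 0 features", call. = FALSE)
  }
  feats
}

# ---- multinomial naive Bayes (no installed package provides it) ----------

fit_nbm <- function(x, y, alpha = 1) {
  classes <- severity_classes()
  logprior <- log(as.numeric(table(factor(y, classes))) + alpha) -
    log(length(y) + 4 * alpha)
  loglik <- t(vapply(classes, function(cl) {
    cnt <- colSums(x[y == cl, , drop = FALSE]) + alpha
    log(cnt) - log(sum(cnt))
  }, numeric(ncol(x))))
  list(logprior = logprior, loglik = loglik, classes = classes)
}

predict_nbm <- function(fit, x) {
  scores <- x %*% t(fit$loglik)
  scores <- sweep(scores, 2L, fit$logprior, `+`)
  fit$classes[max.col(scores, ties.method = "first")]
}

# ---- compact gain-ratio decision tree (C4.5-style, binary presence splits)

tree_split_score <- function(pj, y, h_parent) {
  n <- length(y); n1 <- sum(pj)
  if (n1 == 0L || n1 == n) return(NULL)
  h1 <- entropy_bits(as.numeric(table(y[pj])) / n1)
  h0 <- entropy_bits(as.numeric(table(y[!pj])) / (n - n1))
  gain <- h_parent - (n1 / n) * h1 - (1 - n1 / n) * h0
  split_info <- entropy_bits(c(n1 / n, 1 - n1 / n))
  if (gain <= 1e-12 || split_info <= 1e-12) return(NULL)
  gain / split_info
}

fit_tree_node <- function(present, y, depth, max_depth, min_split) {
  majority <- names(which.max(table(factor(y, severity_classes()))))
  if (depth >= max_depth || length(y) < min_split || length(unique(y)) == 1L) {
    return(list(leaf = TRUE, label = majority))
  }
  h_parent <- entropy_bits(as.numeric(table(y)) / length(y))
  best <- NULL; best_score <- 0
  for (j in seq_len(ncol(present))) {
    sc <- tree_split_score(present[, j], y, h_parent)
    if (!is.null(sc) && sc > best_score + 1e-12) {
      best_score <- sc; best <- j
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, label = majority))
  pj <- present[, best]
  list(leaf = FALSE, feature = colnames(present)[best], label = majority,
       yes = fit_tree_node(present[pj, , drop = FALSE], y[pj],
                           depth + 1L, max_depth, min_split),
       no = fit_tree_node(present[!pj, , drop = FALSE], y[!pj],
                          depth + 1L, max_depth, min_split))
}

predict_tree_one <- function(node, present_row) {
  while (!node$leaf) {
    node <- if (isTRUE(present_row[[node$feature]])) node$yes else node$no
  }
  node$label
}

# ---- fit / predict surface ------------------------------------------------

#' Fit a bag-of-words baseline classifier
#'
#' The three baselines of the source study: `tree` (a C4.5-style gain-ratio
#' decision tree over feature presence), `svm` (a linear large-margin
#' classifier, realised as glmnet's ridge-penalised multinomial model) and
#' `nbm` (multinomial naive Bayes). Features are first filtered by
#' information-gain ranking (default: keep IG > 0).
#'
#' @param table A `feature_table`.
#' @param labels Gold labels (defaults to those in `table`).
#' @param algorithm "tree", "svm" or "nbm".
#' @param selection Feature-selection rule: list with `rule` one of
#'   "ig_positive" (default), "top_k" (+ `k`), "threshold" (+ `threshold`),
#'   "none".
#' @param seed Seed (refits are deterministic given data and seed).
#' @return A `baseline_model` with a [predict()] method returning labels.
#' @export
fit_baseline <- function(table, labels = table$labels,
                         algorithm = c("tree", "svm", "nbm"),
                         selection = list(rule = "ig_positive"),
                         seed = 1) {
  if (is.character(algorithm) && length(algorithm) == 1L &&
      !algorithm %in% c("tree", "svm", "nbm")) {
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  }
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(table, "feature_table"))
  if (anyNA(labels)) stop("every record must be labelled", call. = FALSE)
  ranking <- information_gain_rank(table, labels)
  feats <- select_features(ranking, selection)
  x <- table$counts[, feats, drop = FALSE]
  fit <- with_seed(seed, switch(
    algorithm,
    nbm = fit_nbm(x, labels),
    tree = fit_tree_node(x > 0L, labels, depth = 0L, max_depth = 12L,
                         min_split = 5L),
    svm = {
      xs <- as.matrix(x)
      glmnet::glmnet(xs, factor(labels, severity_classes()),
                     family = "multinomial", alpha = 0,
                     lambda = c(1, 0.1, 0.02), standardize = TRUE)
    }
  ))
  structure(
    list(algorithm = algorithm, features = feats, fit = fit,
         ranking = ranking, seed = seed),
    class = "baseline_model"
  )
}

#' @export
predict.baseline_model <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  missing_feats <- setdiff(object$features, table$features)
  x <- matrix(0L, nrow(table$counts), length(object$features),
              dimnames = list(NULL, object$features))
  common <- intersect(object$features, table$features)
  x[, common] <- table$counts[, common, drop = FALSE]
  if (length(missing_feats) == 0L && length(common) == 0L) {
    stop("feature table shares no features with the model", call. = FALSE)
  }
  pred <- switch(
    object$algorithm,
    nbm = predict_nbm(object$fit, x),
    tree = vapply(seq_len(nrow(x)), function(i) {
      predict_tree_one(object$fit, as.list(x[i, ] > 0L))
    }, character(1)),
    svm = {
      as.character(predict(object$fit, newx = as.matrix(x), s = 0.02,
                           type = "class"))
    }
  )
  data.frame(record_id = table$record_ids, predicted = pred,
             stringsAsFactors = FALSE)
}
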
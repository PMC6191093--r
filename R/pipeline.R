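subset_tokenized <- function(tok, idx) {
  out <- tok
  out$records <- tok$records[idx]
  out
}

#' Fit a model on one tokenized corpus and predict another
#'
#' The shared train/predict step behind cross-validation and train/test
#' splits: the vocabulary is built on the training portion only, the model
#' (a [cnn_spec()] or a baseline name "tree"/"svm"/"nbm") is fitted on it,
#' and the held-out portion is scored with the training-time vocabulary and
#' sequence length.
#'
#' @param train_tok,test_tok `tokenized_corpus` objects.
#' @param model A `cnn_spec` or one of "tree", "svm", "nbm".
#' @param train A [train_config()] (CNN only).
#' @param min_count Vocabulary frequency cutoff.
#' @param max_length Sequence length override (CNN only; default 95th
#'   percentile of training lengths).
#' @return [labeled_predictions()] for the test records.
#' @export
fit_and_predict <- function(train_tok, test_tok, model,
                            train = train_config(), min_count = 1,
                            max_length = NULL) {
  vocab <- build_vocabulary(train_tok, min_count = min_count)
  if (inherits(model, "cnn_spec")) {
    enc_train <- encode_corpus(train_tok, vocab, max_length)
    cnn <- build_cnn(model, vocab, seed = train$seed)
    cnn <- train_cnn(cnn, enc_train, config = train)
    enc_test <- encode_corpus(test_tok, vocab, enc_train$max_length)
    pred <- predict(cnn, enc_test)
  } else if (is.character(model) && length(model) == 1L) {
    ft_train <- bag_of_words(train_tok, vocab)
    clf <- fit_baseline(ft_train, algorithm = model, seed = train$seed)
    pred <- predict(clf, bag_of_words(test_tok, vocab))
  } else {
    stop("`model` must be a cnn_spec or a baseline name", call. = FALSE)
  }
  labeled_predictions(pred$record_id, tokenized_labels(test_tok),
                      pred$predicted)
}

#' Stratified k-fold cross-validation of a model
#'
#' @param tok A labelled `tokenized_corpus`.
#' @param model A `cnn_spec` or baseline name.
#' @param k Number of folds.
#' @param seed Fold-shuffle seed.
#' @param train A [train_config()].
#' @param min_count,max_length Passed to [fit_and_predict()].
#' @return Aggregated `metrics_report` (see [aggregate_fold_metrics()]);
#'   pooled per-record predictions in `attr(, "predictions")`.
#' @export
crossval_model <- function(tok, model, k = 5, seed = 1,
                           train = train_config(), min_count = 1,
                           max_length = NULL) {
  labels <- tokenized_labels(tok)
  fold <- stratified_folds(labels, k = k, seed = seed)
  fold_reports <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    p <- fit_and_predict(subset_tokenized(tok, fold != f),
                         subset_tokenized(tok, fold == f),
                         model, train = train, min_count = min_count,
                         max_length = max_length)
    fold_reports[[f]] <- metrics_report(p)
    preds[[f]] <- p
  }
  out <- aggregate_fold_metrics(fold_reports)
  attr(out, "predictions") <- do.call(rbind, preds)
  out
}

#' Experiment configuration
#'
#' One end-to-end run: corpus source (a directory or a
#' [generator_config()]), preprocessing switches, one model, training
#' hyperparameters and an evaluation scheme.
#'
#' @param corpus A directory path or a `generator_config`.
#' @param preprocess List of switches: `spell`, `refine`,
#'   `normalise_questions` (all default TRUE).
#' @param model A [cnn_spec()] or one of "tree", "svm", "nbm".
#' @param train A [train_config()].
#' @param evaluation List: `method` of "cv" (with `k`, `seed`), "split"
#'   (with `train_fraction`, `seed`) or "resubstitution" (train = test;
#'   training-error probes).
#' @param min_count Vocabulary cutoff.
#' @param output_dir Optional directory for artifacts (config echo, metrics
#'   JSON, predictions TSV, log).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(corpus,
                              preprocess = list(),
                              model = cnn_spec(),
                              train = train_config(),
                              evaluation = list(method = "cv", k = 5, seed = 1),
                              min_count = 1,
                              output_dir = NULL) {
  if (!(inherits(corpus, "generator_config") ||
        (is.character(corpus) && length(corpus) == 1L))) {
    stop("`corpus` must be a directory path or a generator_config",
         call. = FALSE)
  }
  if (!(inherits(model, "cnn_spec") ||
        (is.character(model) && model %in% c("tree", "svm", "nbm")))) {
    stop("`model` must be a cnn_spec or one of tree/svm/nbm", call. = FALSE)
  }
  pp <- utils::modifyList(
    list(spell = TRUE, refine = TRUE, normalise_questions = TRUE), preprocess)
  ev <- utils::modifyList(list(method = "cv", k = 5, seed = 1,
                               train_fraction = 0.8), evaluation)
  if (!ev$method %in% c("cv", "split", "resubstitution")) {
    stop("evaluation method must be cv, split or resubstitution",
         call. = FALSE)
  }
  structure(
    list(corpus = corpus, preprocess = pp, model = model, train = train,
         evaluation = ev, min_count = min_count, output_dir = output_dir),
    class = "experiment_config"
  )
}

stage <- function(log, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
  log(sprintf("%s  stage=%s  elapsed=%.2fs",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

model_descriptor <- function(model) {
  if (inherits(model, "cnn_spec")) {
    list(kind = "cnn",
         region_sizes = model$region_sizes,
         n_feature_maps = model$n_feature_maps,
         pooling = model$pooling,
         chunk_count = model$chunk_count,
         dropout_rate = model$dropout_rate,
         embedding_mode = model$embedding$mode,
         pooled_length = pooled_length(model))
  } else {
    list(kind = "baseline", algorithm = model)
  }
}

#' Run one experiment end to end
#'
#' generate/read -> preprocess -> represent -> train -> predict -> evaluate.
#' Every stage failure is re-raised with the stage name. When the config
#' names an output directory, a config echo, metrics JSON, predictions TSV
#' and a stage-timestamped log are written there.
#'
#' @param config An [experiment_config()].
#' @return The `metrics_report` (aggregated over folds for CV), with the
#'   pooled predictions in `attr(, "predictions")` and the model descriptor
#'   (including the pooled-vector length for CNNs) in `attr(, "model")`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  log_lines <- character(0)
  log <- function(line) log_lines <<- c(log_lines, line)

  corpus <- stage(log, "corpus", {
    if (inherits(config$corpus, "generator_config")) {
      generate_corpus(config$corpus)
    } else {
      read_corpus(config$corpus)
    }
  })
  tok <- stage(log, "preprocess", {
    t <- preprocess_corpus(corpus, spell = config$preprocess$spell,
                           refine = config$preprocess$refine)
    if (config$preprocess$normalise_questions) t <- normalise_questions(t)
    t
  })
  ev <- config$evaluation
  report <- stage(log, "evaluate", {
    if (ev$method == "cv") {
      crossval_model(tok, config$model, k = ev$k, seed = ev$seed,
                     train = config$train, min_count = config$min_count)
    } else if (ev$method == "split") {
      labels <- tokenized_labels(tok)
      k <- max(2L, round(1 / (1 - ev$train_fraction)))
      fold <- stratified_folds(labels, k = k, seed = ev$seed)
      p <- fit_and_predict(subset_tokenized(tok, fold != 1L),
                           subset_tokenized(tok, fold == 1L),
                           config$model, train = config$train,
                           min_count = config$min_count)
      r <- metrics_report(p)
      attr(r, "predictions") <- p
      r
    } else { # resubstitution
      p <- fit_and_predict(tok, tok, config$model, train = config$train,
                           min_count = config$min_count)
      r <- metrics_report(p)
      attr(r, "predictions") <- p
      r
    }
  })
  attr(report, "model") <- model_descriptor(config$model)
  if (inherits(config$model, "cnn_spec")) {
    log(sprintf("pooled vector length = %d", pooled_length(config$model)))
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    echo <- config
    echo$model <- model_descriptor(config$model)
    jsonlite::write_json(
      lapply(unclass(echo), function(x) if (is.list(x)) unclass(x) else x),
      file.path(config$output_dir, "config.json"),
      auto_unbox = TRUE, null = "null", force = TRUE, pretty = TRUE)
    jsonlite::write_json(
      list(per_class_mae = as.list(report$per_class_mae),
           mmae = report$mmae, nmae = report$nmae,
           n_per_class = as.list(report$n_per_class),
           model = attr(report, "model")),
      file.path(config$output_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_predictions(attr(report, "predictions"),
                      file.path(config$output_dir, "predictions.tsv"))
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  attr(report, "log") <- log_lines
  report
}

#' Run a grid of experiments and summarise
#'
#' @param configs List of [experiment_config()] objects.
#' @param baseline Index of the config whose MMAE anchors the
#'   `delta_mmae` column (change-in-MAE relative to a named baseline run).
#' @param path Optional TSV output path for the summary.
#' @return Data frame with one row per config: model, region sizes, maps,
#'   pooling, mmae, nmae, delta_mmae.
#' @export
run_grid <- function(configs, baseline = 1L, path = NULL) {
  stopifnot(length(configs) >= 1L)
  rows <- lapply(configs, function(cfg) {
    rep <- run_experiment(cfg)
    md <- attr(rep, "model")
    data.frame(
      model = if (md$kind == "cnn") "cnn" else md$algorithm,
      region_sizes = if (md$kind == "cnn") {
        paste0("{", paste(md$region_sizes, collapse = ","), "}")
      } else NA_character_,
      n_feature_maps = if (md$kind == "cnn") md$n_feature_maps else NA_integer_,
      pooling = if (md$kind == "cnn") md$pooling else NA_character_,
      mmae = rep$mmae, nmae = rep$nmae,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_mmae <- out$mmae - out$mmae[baseline]
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
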
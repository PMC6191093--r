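#' Assemble labeled predictions
#'
#' @param record_id Record identifiers.
#' @param gold Gold severity labels.
#' @param predicted Predicted severity labels.
#' @return A data.frame with class `labeled_predictions` (columns record_id,
#'   gold, predicted); both label columns are validated against the scale.
#' @export
labeled_predictions <- function(record_id, gold, predicted) {
  severity_score(gold); severity_score(predicted)  # validate
  out <- data.frame(record_id = as.character(record_id),
                    gold = as.character(gold),
                    predicted = as.character(predicted),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_predictions", class(out))
  out
}

#' Per-class mean absolute error
#'
#' Mean of |predicted score - gold score| over the records whose gold class
#' is `class`; the distance is the same whether scores are taken as 1..4 or
#' 0..3 (only differences enter).
#'
#' @param predictions A [labeled_predictions()] data.frame.
#' @param class One of the four severity labels.
#' @return MAE for that class, in \[0, 3\].
#' @export
class_mae <- function(predictions, class) {
  stopifnot(class %in% severity_classes())
  sel <- predictions$gold == class
  if (!any(sel)) {
    stop("no gold records of class ", class, "; per-class MAE is undefined",
         call. = FALSE)
  }
  mean(abs(severity_score(predictions$predicted[sel]) -
             severity_score(predictions$gold[sel])))
}

#' Macro-averaged MAE
#'
#' Unweighted mean of the four per-class MAEs, guarding the overall score
#' against class imbalance. All four classes must be present among the gold
#' labels.
#'
#' @param predictions A [labeled_predictions()] data.frame.
#' @return MMAE.
#' @export
mmae <- function(predictions) {
  mmae_from_class_maes(vapply(severity_classes(), class_mae,
                              numeric(1), predictions = predictions))
}

#' @rdname mmae
#' @param per_class Numeric vector of 4 per-class MAEs in class order.
#' @export
mmae_from_class_maes <- function(per_class) {
  if (length(per_class) != 4L || anyNA(per_class)) {
    stop("need 4 per-class MAEs (all classes present)", call. = FALSE)
  }
  mean(per_class)
}

#' Normalised macro-averaged MAE
#'
#' Each class's deviations are divided by that class's maximum possible
#' deviation, `max(score - 1, 4 - score)` = (3, 2, 2, 3), macro-averaged and
#' subtracted from 1, so 1 is perfect and 0 is the always-farthest
#' predictor. Because the normaliser is constant within a class, computing
#' from per-record deviations or from per-class MAEs agrees exactly.
#'
#' @param predictions A [labeled_predictions()] data.frame.
#' @return NMAE in \[0, 1\].
#' @export
nmae <- function(predictions) {
  nmae_from_class_maes(vapply(severity_classes(), class_mae,
                              numeric(1), predictions = predictions))
}

#' @rdname nmae
#' @param per_class Numeric vector of 4 per-class MAEs in class order.
#' @export
nmae_from_class_maes <- function(per_class) {
  if (length(per_class) != 4L || anyNA(per_class)) {
    stop("need 4 per-class MAEs (all classes present)", call. = FALSE)
  }
  1 - mean(per_class / severity_normaliser(severity_classes()))
}

#' Per-record score-distance table
#'
#' One row per record with gold score, predicted score and their absolute
#' distance, stably sorted by gold score ascending (the layout behind
#' per-record error charts).
#'
#' @param predictions A [labeled_predictions()] data.frame.
#' @return Data frame: record_id, gold_score, predicted_score, distance.
#' @export
distance_table <- function(predictions) {
  g <- severity_score(predictions$gold)
  p <- severity_score(predictions$predicted)
  out <- data.frame(record_id = predictions$record_id,
                    gold_score = g, predicted_score = p,
                    distance = abs(p - g), stringsAsFactors = FALSE)
  out <- out[order(out$gold_score), , drop = FALSE]  # stable sort
  rownames(out) <- NULL
  out
}

#' Full metrics report
#'
#' @param predictions A [labeled_predictions()] data.frame.
#' @return A `metrics_report`: per_class_mae (named), mmae, nmae,
#'   n_per_class, distance_table.
#' @export
metrics_report <- function(predictions) {
  per_class <- vapply(severity_classes(), class_mae, numeric(1),
                      predictions = predictions)
  structure(
    list(per_class_mae = per_class,
         mmae = mmae_from_class_maes(per_class),
         nmae = nmae_from_class_maes(per_class),
         n_per_class = stats::setNames(as.integer(
           table(factor(predictions$gold, severity_classes()))),
           severity_classes()),
         distance_table = distance_table(predictions)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat("  per-class MAE:",
      paste(sprintf("%s=%.3f", names(x$per_class_mae),
                    round_half_up(x$per_class_mae)), collapse = "  "), "\n")
  cat(sprintf("  MMAE = %.3f   NMAE = %.3f\n",
              round_half_up(x$mmae), round_half_up(x$nmae)))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Partitions records into k folds such that per-class counts across folds
#' differ by at most one; the shuffle is seeded.
#'
#' @param labels Gold labels (all labelled).
#' @param k Number of folds (>= 2, at most the smallest class count).
#' @param seed Shuffle seed.
#' @return Integer fold assignment (1..k) per record.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  k <- assert_count(k, "k")
  if (k < 2L) stop("k must be >= 2 (k = 1 leaves no held-out data)",
                   call. = FALSE)
  if (anyNA(labels)) stop("all records must be labelled", call. = FALSE)
  counts <- table(factor(labels, severity_classes()))
  if (k > min(counts)) {
    stop(sprintf("k = %d exceeds the smallest class count (%d)",
                 k, min(counts)), call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in severity_classes()) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Average fold-level metrics
#'
#' Cross-validation aggregation convention: metrics are computed per fold,
#' then averaged (per-class MAEs, MMAE and NMAE element-wise).
#'
#' @param fold_reports List of `metrics_report` objects.
#' @return A `metrics_report`-like list (distance tables concatenated).
#' @export
aggregate_fold_metrics <- function(fold_reports) {
  per_class <- colMeans(do.call(rbind, lapply(fold_reports, `[[`,
                                              "per_class_mae")))
  structure(
    list(per_class_mae = per_class,
         mmae = mean(vapply(fold_reports, `[[`, numeric(1), "mmae")),
         nmae = mean(vapply(fold_reports, `[[`, numeric(1), "nmae")),
         n_per_class = Reduce(`+`, lapply(fold_reports, `[[`, "n_per_class")),
         distance_table = do.call(rbind, lapply(fold_reports, `[[`,
                                                "distance_table")),
         per_fold = fold_reports),
    class = "metrics_report"
  )
}
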
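#' Construct a psychiatric evaluation record
#'
#' A record is the unit of classification: free text assembled from ordered
#' segments of three kinds observed in initial psychiatric evaluations —
#' `narrative` (headed unstructured prose), `attribute_value` (list-like
#' "Attribute: value" lines) and `qa_template` (a heading followed by
#' question-answer pairs). The raw text is, by construction, the
#' concatenation of the segment texts in order.
#'
#' @param record_id Unique identifier string.
#' @param segments A data.frame with columns `kind` (one of `"narrative"`,
#'   `"attribute_value"`, `"qa_template"`) and `text`.
#' @param gold_label Severity label, or `NA` for an unlabelled record.
#' @return An object of class `psych_record`.
#' @export
psychiatric_record <- function(record_id, segments, gold_label = NA_character_) {
  stopifnot(is.character(record_id), length(record_id) == 1L, nzchar(record_id))
  if (!is.data.frame(segments) || !all(c("kind", "text") %in% names(segments))) {
    stop("`segments` must be a data.frame with columns kind, text", call. = FALSE)
  }
  kinds <- c("narrative", "attribute_value", "qa_template")
  if (!all(segments$kind %in% kinds)) {
    stop("segment kind must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  if (!is.na(gold_label) && !gold_label %in% severity_classes()) {
    stop("gold_label must be one of ", paste(severity_classes(), collapse = "/"),
         " or NA", call. = FALSE)
  }
  structure(
    list(
      record_id = record_id,
      raw_text = paste(segments$text, collapse = ""),
      gold_label = as.character(gold_label),
      segments = segments[, c("kind", "text")]
    ),
    class = "psych_record"
  )
}

#' Construct a corpus of records
#'
#' @param records List of [psychiatric_record()] objects with unique ids.
#' @return An object of class `psych_corpus`.
#' @export
psych_corpus <- function(records) {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) {
    stop("record_id values must be unique within a corpus", call. = FALSE)
  }
  structure(list(records = records), class = "psych_corpus")
}

#' @export
length.psych_corpus <- function(x) length(x$records)

#' Count of labelled records per severity class
#'
#' @param corpus A `psych_corpus`.
#' @return Named integer vector over the four classes (unlabelled records are
#'   not counted).
#' @export
label_distribution <- function(corpus) {
  labs <- corpus_labels(corpus)
  tab <- table(factor(labs[!is.na(labs)], levels = severity_classes()))
  stats::setNames(as.integer(tab), severity_classes())
}

#' Gold labels of a corpus, in record order
#' @param corpus A `psych_corpus`.
#' @return Character vector (NA for unlabelled records).
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus$records, function(r) r$gold_label, character(1))
}

#' @export
print.psych_corpus <- function(x, ...) {
  cat(sprintf("<psych_corpus> %d records\n", length(x)))
  print(label_distribution(x))
  invisible(x)
}

#' Write a corpus to a directory
#'
#' One UTF-8 `.txt` file per record plus a `labels.tsv` (columns `record_id`,
#' `label`; empty label for unlabelled records) and a `manifest.json` echoing
#' record and class counts (and the generator configuration, when the corpus
#' was synthesised). Reading the directory back with [read_corpus()] restores
#' raw text, record order and labels exactly.
#'
#' @param corpus A `psych_corpus`.
#' @param directory Target directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_corpus <- function(corpus, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  labs <- corpus_labels(corpus)
  ids <- vapply(corpus$records, function(r) r$record_id, character(1))
  for (r in corpus$records) {
    con <- file(file.path(directory, paste0(r$record_id, ".txt")),
                open = "wb")
    writeBin(charToRaw(enc2utf8(r$raw_text)), con)
    close(con)
  }
  lab_df <- data.frame(record_id = ids,
                       label = ifelse(is.na(labs), "", labs),
                       stringsAsFactors = FALSE)
  utils::write.table(lab_df, file.path(directory, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    n_records = length(corpus),
    class_counts = as.list(label_distribution(corpus)),
    generator_config = attr(corpus, "generator_config")
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Read a corpus from a directory
#'
#' @param directory Directory produced by [write_corpus()] (or any directory
#'   holding one `.txt` per record and a `labels.tsv`).
#' @return A `psych_corpus`; each record carries a single narrative segment
#'   holding the full raw text.
#' @export
read_corpus <- function(directory) {
  lab_path <- file.path(directory, "labels.tsv")
  if (!file.exists(lab_path)) {
    stop("missing label file: ", lab_path, call. = FALSE)
  }
  lab <- utils::read.delim(lab_path, colClasses = "character")
  bad <- setdiff(lab$label[nzchar(lab$label)], severity_classes())
  if (length(bad)) {
    stop("invalid severity label(s) in labels.tsv: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  records <- lapply(seq_len(nrow(lab)), function(i) {
    path <- file.path(directory, paste0(lab$record_id[i], ".txt"))
    if (!file.exists(path)) {
      stop("missing record file: ", path, call. = FALSE)
    }
    txt <- rawToChar(readBin(path, "raw", n = file.size(path)))
    Encoding(txt) <- "UTF-8"
    psychiatric_record(
      record_id = lab$record_id[i],
      segments = data.frame(kind = "narrative", text = txt,
                            stringsAsFactors = FALSE),
      gold_label = if (nzchar(lab$label[i])) lab$label[i] else NA_character_
    )
  })
  psych_corpus(records)
}
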
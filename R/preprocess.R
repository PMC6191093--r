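#' Bundled misspelling dictionary
#'
#' A pluggable stand-in for an external spell checker: a frequency table of
#' misspellings observed in clinical text mapped to their corrections. Any
#' named character vector (misspelling -> correction) can be supplied to
#' [correct_spelling()] in its place.
#'
#' @return Named character vector, names are misspellings.
#' @export
default_misspellings <- function() {
  path <- system.file("extdata", "misspellings.tsv", package = "sevcnn")
  tab <- utils::read.delim(path, colClasses = "character")
  stats::setNames(tab$correction, tab$misspelling)
}

#' Correct frequently misspelled words
#'
#' Whole-word replacements only; idempotent provided no correction is itself
#' listed as a misspelling (true of the bundled table). Words absent from the
#' table are untouched.
#'
#' @param text Character vector of text.
#' @param dictionary Named character vector, misspelling -> correction.
#' @return Corrected text.
#' @export
correct_spelling <- function(text, dictionary = default_misspellings()) {
  if (length(dictionary) == 0L) return(text)
  if (is.null(names(dictionary)) || any(!nzchar(names(dictionary)))) {
    stop("`dictionary` must be a named vector (misspelling -> correction)",
         call. = FALSE)
  }
  for (bad in names(dictionary)) {
    text <- gsub(paste0("\\b", bad, "\\b"), dictionary[[bad]], text,
                 perl = TRUE)
  }
  text
}

#' Tokenise text into words and punctuation marks
#'
#' Alphanumeric runs form word tokens; every other non-space character is a
#' single-character token. Joining the tokens with single spaces re-reads as
#' the same word sequence.
#'
#' @param text A single string (UTF-8).
#' @return Character vector of tokens (empty for empty input).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", text)
  regmatches(text, m)[[1]]
}

#' Split merged tokens at case and digit boundaries
#'
#' Every lowercase-to-uppercase boundary and digit-to-letter boundary inside
#' a token becomes a split point, applied exhaustively: "PsychiatryChief" ->
#' "Psychiatry", "Chief"; "10mgDaily" -> "10", "mg", "Daily". Idempotent, and
#' a left inverse of the fusions emitted by [inject_noise()].
#'
#' @param tokens Character vector of tokens.
#' @return Refined token vector (possibly longer).
#' @export
refine_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(tokens)
  s <- tokens
  repeat {
    s2 <- gsub("([a-z])([A-Z])", "\\1 \\2", s)
    s2 <- gsub("([0-9])([A-Za-z])", "\\1 \\2", s2)
    if (identical(s2, s)) break
    s <- s2
  }
  out <- unlist(strsplit(s, " ", fixed = TRUE), use.names = FALSE)
  out[nzchar(out)]
}

#' Default extraction patterns for semi-structured lines
#'
#' Perl regexes with named groups `question` and `answer`, tried in order on
#' each line: "question? : answer", "question?: answer", and the
#' attribute-value form "attribute: value". Shipped as an editable character
#' vector; a rule lacking either named group is rejected at load time.
#'
#' @return Character vector of perl-compatible regexes.
#' @export
default_qa_patterns <- function() {
  c(
    qa = "^(?<question>[^\\r\\n]*?\\?)[ \\t]*:[ \\t]*(?<answer>\\S[^\\r\\n]*?)[ \\t]*$",
    av = "^(?<question>[A-Za-z][A-Za-z0-9 /'-]{1,60}?)[ \\t]*:[ \\t]*(?<answer>\\S[^\\r\\n]*?)[ \\t]*$"
  )
}

validate_qa_patterns <- function(patterns) {
  if (length(patterns) == 0L) {
    stop("QA pattern rule set must be non-empty", call. = FALSE)
  }
  for (p in patterns) {
    if (!grepl("(?<question>", p, fixed = TRUE) ||
        !grepl("(?<answer>", p, fixed = TRUE)) {
      stop("malformed QA rule (needs named groups 'question' and 'answer'): ",
           p, call. = FALSE)
    }
    ok <- tryCatch({regexpr(p, "x", perl = TRUE); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("malformed QA rule (invalid regex): ", p, call. = FALSE)
  }
  invisible(patterns)
}

#' Extract question-answer and attribute-value pairs from record text
#'
#' Applies the rule set line by line; the first matching rule wins. Each
#' matched line yields one pair with 0-based half-open character spans into
#' `text` (whole line, and the question part alone). Short forms Q1, Q2, ...
#' are assigned in order of appearance within the text; [normalise_questions()]
#' later rewrites them under a corpus-global mapping.
#'
#' @param text Record text.
#' @param patterns Rule set, see [default_qa_patterns()].
#' @return List with `pairs` (data.frame: question, answer, short_form,
#'   start, end, q_start, q_end) and `residual` (text with matched lines
#'   removed).
#' @export
extract_qa_pairs <- function(text, patterns = default_qa_patterns()) {
  validate_qa_patterns(patterns)
  lines <- strsplit(paste0(text, "\n"), "\n", fixed = TRUE)[[1]]
  offsets <- c(0L, cumsum(nchar(lines) + 1L))
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) next
    for (p in patterns) {
      m <- regexpr(p, line, perl = TRUE)
      if (m > 0L) {
        cs <- attr(m, "capture.start")[1, ]
        cl <- attr(m, "capture.length")[1, ]
        q <- substr(line, cs[["question"]], cs[["question"]] + cl[["question"]] - 1L)
        a <- substr(line, cs[["answer"]], cs[["answer"]] + cl[["answer"]] - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          question = q, answer = a, short_form = NA_character_,
          start = offsets[i], end = offsets[i] + nchar(line),
          q_start = offsets[i] + cs[["question"]] - 1L,
          q_end = offsets[i] + cs[["question"]] + cl[["question"]] - 1L,
          stringsAsFactors = FALSE
        )
        break
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    question = character(0), answer = character(0),
    short_form = character(0), start = integer(0), end = integer(0),
    q_start = integer(0), q_end = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(pairs)) pairs$short_form <- paste0("Q", seq_len(nrow(pairs)))
  residual <- text
  if (nrow(pairs)) {
    for (i in rev(seq_len(nrow(pairs)))) {
      residual <- paste0(substr(residual, 1L, pairs$start[i]),
                         substr(residual, pairs$end[i] + 2L, nchar(residual)))
    }
  }
  list(pairs = pairs, residual = residual)
}

tokenize_record_text <- function(text, refine = TRUE) {
  toks <- tokenize(text)
  if (refine) toks <- refine_tokens(toks)
  toks
}

#' Pre-process a corpus into token sequences
#'
#' The pipeline of the source task: optional whole-word spell correction,
#' tokenisation, optional merged-token refinement, and extraction of
#' question-answer / attribute-value pairs. Question normalisation is a
#' separate corpus-level step ([normalise_questions()]) because short forms
#' are assigned corpus-globally.
#'
#' @param corpus A `psych_corpus`.
#' @param spell Apply [correct_spelling()] first.
#' @param refine Apply [refine_tokens()] after tokenisation.
#' @param dictionary Misspelling dictionary for `spell`.
#' @param patterns QA extraction rules.
#' @param normalise_questions Convenience switch: run [normalise_questions()]
#'   on the result.
#' @return A `tokenized_corpus`: list of records each holding `record_id`,
#'   `text` (post-correction), `tokens`, `qa_pairs`, `label`; attributes
#'   `normalised` (flag), `refine` and `question_map`.
#' @export
preprocess_corpus <- function(corpus, spell = TRUE, refine = TRUE,
                              dictionary = default_misspellings(),
                              patterns = default_qa_patterns(),
                              normalise_questions = FALSE) {
  stopifnot(inherits(corpus, "psych_corpus"))
  validate_qa_patterns(patterns)
  recs <- lapply(corpus$records, function(r) {
    txt <- r$raw_text
    if (spell) txt <- correct_spelling(txt, dictionary)
    ex <- extract_qa_pairs(txt, patterns)
    list(record_id = r$record_id,
         text = txt,
         tokens = tokenize_record_text(txt, refine = refine),
         qa_pairs = ex$pairs,
         label = r$gold_label)
  })
  out <- structure(list(records = recs), class = "tokenized_corpus")
  attr(out, "normalised") <- FALSE
  attr(out, "refine") <- refine
  attr(out, "question_map") <- NULL
  if (normalise_questions) out <- sevcnn::normalise_questions(out)
  out
}

#' @export
length.tokenized_corpus <- function(x) length(x$records)

#' Labels of a tokenized corpus, in record order
#' @param tok A `tokenized_corpus`.
#' @return Character vector.
#' @export
tokenized_labels <- function(tok) {
  vapply(tok$records, function(r) r$label, character(1))
}

#' Normalise questions to corpus-global short forms
#'
#' Each distinct question string maps to one short form Qk, numbered by first
#' appearance scanning records in corpus order (so the same question receives
#' the same token in every record). Record token streams are re-derived with
#' each question's text replaced, in place, by its short form; character
#' spans keep referring to the stored (post-correction) text.
#'
#' @param tok A `tokenized_corpus` from [preprocess_corpus()].
#' @return The normalised `tokenized_corpus`, with the question -> short-form
#'   mapping in `attr(, "question_map")`.
#' @export
normalise_questions <- function(tok) {
  stopifnot(inherits(tok, "tokenized_corpus"))
  if (isTRUE(attr(tok, "normalised"))) return(tok)
  qmap <- character(0)
  for (r in tok$records) {
    for (q in r$qa_pairs$question) {
      if (!q %in% names(qmap)) {
        qmap[q] <- paste0("Q", length(qmap) + 1L)
      }
    }
  }
  refine <- isTRUE(attr(tok, "refine"))
  tok$records <- lapply(tok$records, function(r) {
    pairs <- r$qa_pairs
    if (nrow(pairs)) {
      pairs$short_form <- unname(qmap[pairs$question])
      txt <- r$text
      for (i in rev(seq_len(nrow(pairs)))) {
        txt <- paste0(substr(txt, 1L, pairs$q_start[i]),
                      pairs$short_form[i],
                      substr(txt, pairs$q_end[i] + 1L, nchar(txt)))
      }
      r$qa_pairs <- pairs
      r$tokens <- tokenize_record_text(txt, refine = refine)
    }
    r
  })
  attr(tok, "normalised") <- TRUE
  attr(tok, "question_map") <- qmap
  tok
}

#' Write the question normalisation mapping as a TSV audit file
#'
#' @param tok A normalised `tokenized_corpus`.
#' @param path Output path.
#' @return Invisibly, the mapping data.frame.
#' @export
write_question_map <- function(tok, path) {
  qmap <- attr(tok, "question_map")
  if (is.null(qmap)) stop("corpus has not been question-normalised", call. = FALSE)
  df <- data.frame(question = names(qmap), short_form = unname(qmap),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
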
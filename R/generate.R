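#' Noise model configuration for synthetic records
#'
#' Real evaluation records contain words merged together (e.g.
#' "PsychiatryChief" for "Psychiatry Chief") and frequent misspellings. The
#' generator injects both at configurable rates; every fusion it emits is a
#' lowercase-to-uppercase or digit-to-letter join, so the preprocessing
#' refinement rules invert it exactly.
#'
#' @param merge_rate Probability that an eligible adjacent token pair is fused.
#' @param misspell_rate Probability that a word with an entry in the bundled
#'   misspelling table is perturbed.
#' @return A `noise_config` list.
#' @export
noise_config <- function(merge_rate = 0.02, misspell_rate = 0.02) {
  assert_probability(merge_rate, "merge_rate")
  assert_probability(misspell_rate, "misspell_rate")
  structure(list(merge_rate = merge_rate, misspell_rate = misspell_rate),
            class = "noise_config")
}

#' Generator configuration for synthetic corpora
#'
#' Defaults restate the training-set world of the source task: 433 records
#' with class proportions 14.08 / 38.33 / 25.4 / 22.17 percent over
#' ABSENT / MILD / MODERATE / SEVERE. Class counts are apportioned by
#' largest-remainder rounding (ties broken by class order), which reproduces
#' the published counts (61, 166, 110, 96) exactly.
#'
#' @param n_records Number of records.
#' @param class_proportions Four probabilities summing to 1 (within 1e-9).
#' @param n_questions Number of distinct template questions per record
#'   (at most `nrow` of the bundled 12-question bank).
#' @param cue_strength Probability in \[0, 1\] that each narrative cue slot
#'   emits a class-specific cue token; also scales how strongly template
#'   answers correlate with the gold class. At 0 the text carries no class
#'   signal at all; at 1 classes are ordinally separable.
#' @param adjacent_share Probability that an emitted cue is drawn from an
#'   ordinally adjacent class's lexicon instead of the record's own class,
#'   producing the adjacent-class confusion structure seen in real data.
#' @param n_sentences Narrative sentences per record (record-length knob; the
#'   source task does not publish a length distribution).
#' @param noise A [noise_config()].
#' @param seed Master seed; all stochastic draws flow from named per-record
#'   substreams of it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_records = 433,
                             class_proportions = c(0.1408, 0.3833, 0.2540, 0.2217),
                             n_questions = 10,
                             cue_strength = 0.7,
                             adjacent_share = 0.2,
                             n_sentences = 6,
                             noise = noise_config(),
                             seed = 1) {
  n_records <- assert_count(n_records, "n_records")
  if (!is.numeric(class_proportions) || length(class_proportions) != 4L ||
      any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 2e-3) {
    # tolerance covers printed percentage tables, which truncate to 2 dp
    stop("`class_proportions` must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  n_questions <- assert_count(n_questions, "n_questions")
  if (n_questions > nrow(.sev_question_bank)) {
    stop("`n_questions` exceeds the bundled question bank (",
         nrow(.sev_question_bank), ")", call. = FALSE)
  }
  assert_probability(cue_strength, "cue_strength")
  assert_probability(adjacent_share, "adjacent_share")
  n_sentences <- assert_count(n_sentences, "n_sentences")
  stopifnot(inherits(noise, "noise_config"))
  structure(
    list(n_records = n_records, class_proportions = class_proportions,
         n_questions = n_questions, cue_strength = cue_strength,
         adjacent_share = adjacent_share, n_sentences = n_sentences,
         noise = noise, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Largest-remainder apportionment of class counts
#'
#' @param n Total count to apportion.
#' @param proportions Non-negative proportions summing to 1.
#' @return Integer counts summing to `n`; remainder seats go to the largest
#'   fractional parts, ties broken by position order.
#' @export
largest_remainder_counts <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(-(quota - counts), seq_along(quota))[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

sample_one <- function(x, prob = NULL) {
  x[sample.int(length(x), 1L, prob = prob)]
}

draw_answer <- function(class_idx, polarity, cue_strength) {
  prof <- if (polarity == "coping") {
    .sev_answer_profile[5L - class_idx, ]
  } else {
    .sev_answer_profile[class_idx, ]
  }
  p <- cue_strength * prof + (1 - cue_strength) * 0.25
  sample_one(.sev_answers, prob = p)
}

draw_cue <- function(class_idx, adjacent_share) {
  k <- class_idx
  if (stats::runif(1) < adjacent_share) {
    nb <- c(k - 1L, k + 1L)
    nb <- nb[nb >= 1L & nb <= 4L]
    k <- sample_one(nb)
  }
  sample_one(.sev_cue_lexicons[[k]])
}

make_sentence <- function(class_idx, config, zipf_prob) {
  n_bg <- sample.int(7L, 1L) + 5L # 6..12 background tokens
  words <- sample(.sev_background_vocab, n_bg, replace = TRUE, prob = zipf_prob)
  for (slot in 1:2) {
    if (stats::runif(1) < config$cue_strength) {
      pos <- sample.int(length(words) + 1L, 1L)
      words <- append(words, draw_cue(class_idx, config$adjacent_share),
                      after = pos - 1L)
    }
  }
  if (stats::runif(1) < 0.35) {
    words <- c(words, sample_one(.sev_phrase_bank))
  }
  words <- unlist(words)
  words[1] <- paste0(toupper(substr(words[1], 1, 1)), substring(words[1], 2))
  paste0(paste(words, collapse = " "), ".")
}

generate_record <- function(record_id, label, config, zipf_prob) {
  class_idx <- severity_score(label)

  sentences <- vapply(seq_len(config$n_sentences), function(i) {
    make_sentence(class_idx, config, zipf_prob)
  }, character(1))
  narrative <- paste0("HISTORY OF PRESENT ILLNESS:\n",
                      paste(sentences, collapse = " "), "\n\n")

  n_attr <- sample.int(2L, 1L) + 2L # 3..4 attribute lines
  attr_names <- sample(names(.sev_attribute_bank), n_attr)
  attr_lines <- vapply(attr_names, function(a) {
    paste0(a, ": ", sample_one(.sev_attribute_bank[[a]]))
  }, character(1))
  attribute_value <- paste0("CURRENT STATUS:\n",
                            paste(attr_lines, collapse = "\n"), "\n\n")

  qs <- .sev_question_bank[seq_len(config$n_questions), ]
  qa_lines <- vapply(seq_len(nrow(qs)), function(i) {
    ans <- draw_answer(class_idx, qs$polarity[i], config$cue_strength)
    paste0(qs$question[i], " : ", ans)
  }, character(1))
  qa_template <- paste0("CLINICAL QUESTIONNAIRE:\n",
                        paste(qa_lines, collapse = "\n"), "\n")

  psychiatric_record(
    record_id = record_id,
    segments = data.frame(
      kind = c("narrative", "attribute_value", "qa_template"),
      text = c(narrative, attribute_value, qa_template),
      stringsAsFactors = FALSE
    ),
    gold_label = label
  )
}

#' Generate a seeded synthetic corpus of psychiatric evaluation records
#'
#' Each record contains a narrative segment (headed prose with
#' class-conditional cue tokens), an attribute-value segment, and a
#' question-answer template segment whose answers ("Yes"/"No"/"None"/
#' "Uncertain") correlate with the gold class in proportion to
#' `cue_strength`. Identical configuration (including seed) yields a
#' byte-identical corpus.
#'
#' @param config A [generator_config()].
#' @return A `psych_corpus` with the generator config attached as an
#'   attribute (echoed into the manifest by [write_corpus()]).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  counts <- largest_remainder_counts(config$n_records, config$class_proportions)
  labels <- rep(severity_classes(), counts)
  labels <- with_seed(substream_seed(config$seed, 0L, 1L), sample(labels))
  zipf_prob <- 1 / seq_along(.sev_background_vocab)
  zipf_prob <- zipf_prob / sum(zipf_prob)

  records <- lapply(seq_len(config$n_records), function(i) {
    rec <- with_seed(
      substream_seed(config$seed, i, 2L),
      generate_record(sprintf("rec%04d", i), labels[i], config, zipf_prob)
    )
    if (config$noise$merge_rate > 0 || config$noise$misspell_rate > 0) {
      rec <- inject_noise(rec, config$noise,
                          seed = substream_seed(config$seed, i, 3L))
    }
    rec
  })
  corpus <- psych_corpus(records)
  attr(corpus, "generator_config") <- config[setdiff(names(config), "noise")]
  attr(corpus, "generator_config")$noise <- unclass(config$noise)
  corpus
}

fusible_pair <- function(w1, w2) {
  (grepl("[a-z]$", w1) && grepl("^[A-Z]", w2)) ||
    (grepl("[0-9]$", w1) && grepl("^[A-Za-z]", w2))
}

inject_noise_line <- function(line, noise, inverse_table) {
  if (!nzchar(line)) return(line)
  words <- strsplit(line, " ", fixed = TRUE)[[1]]
  # misspellings first: whole lowercase words with a known perturbation
  if (noise$misspell_rate > 0) {
    for (i in seq_along(words)) {
      w <- words[i]
      if (w %in% names(inverse_table) && stats::runif(1) < noise$misspell_rate) {
        words[i] <- inverse_table[[w]]
      }
    }
  }
  # then fusions of adjacent eligible pairs (camel-case or digit-letter)
  if (noise$merge_rate > 0 && length(words) > 1L) {
    out <- character(0)
    i <- 1L
    while (i <= length(words)) {
      if (i < length(words) && fusible_pair(words[i], words[i + 1L]) &&
          stats::runif(1) < noise$merge_rate) {
        out <- c(out, paste0(words[i], words[i + 1L]))
        i <- i + 2L
      } else {
        out <- c(out, words[i])
        i <- i + 1L
      }
    }
    words <- out
  }
  paste(words, collapse = " ")
}

#' Inject merged-token and misspelling noise into a record
#'
#' Fuses adjacent token pairs into camel-case ("Psychiatry Chief" ->
#' "PsychiatryChief") or digit-letter forms ("20 mg" -> "20mg") at
#' `merge_rate`, and perturbs words listed in the bundled misspelling table
#' at `misspell_rate`. All emitted fusions are reversible by
#' [refine_tokens()]; all misspellings by [correct_spelling()].
#'
#' @param record A `psych_record`.
#' @param noise A [noise_config()].
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @return The perturbed `psych_record` (raw text rebuilt from segments).
#' @export
inject_noise <- function(record, noise, seed = 1) {
  stopifnot(inherits(record, "psych_record"), inherits(noise, "noise_config"))
  if (noise$merge_rate == 0 && noise$misspell_rate == 0) return(record)
  tab <- default_misspellings()
  inverse_table <- as.list(stats::setNames(names(tab), unname(tab)))
  inverse_table <- inverse_table[!duplicated(names(inverse_table))]
  segs <- record$segments
  with_seed(seed, {
    for (s in seq_len(nrow(segs))) {
      txt <- segs$text[s]
      body <- sub("\n+$", "", txt)
      trailing <- substr(txt, nchar(body) + 1L, nchar(txt))
      lines <- if (nzchar(body)) strsplit(body, "\n", fixed = TRUE)[[1]] else character(0)
      lines <- vapply(lines, inject_noise_line, character(1),
                      noise = noise, inverse_table = inverse_table,
                      USE.NAMES = FALSE)
      segs$text[s] <- paste0(paste(lines, collapse = "\n"), trailing)
    }
  })
  psychiatric_record(record$record_id, segs, record$gold_label)
}
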
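test_that("spell correction replaces whole words only and is idempotent", {
  dict <- c(pateint = "patient", depresion = "depression")
  expect_identical(correct_spelling("pateint reports", dict), "patient reports")
  expect_identical(correct_spelling("inpateintcare", dict), "inpateintcare")
  expect_identical(correct_spelling("depression", dict), "depression")
  expect_identical(correct_spelling("some text", character(0)), "some text")
  once <- correct_spelling("pateint has depresion", dict)
  expect_identical(correct_spelling(once, dict), once)
})

test_that("tokenizer splits words and punctuation, preserving clinical shorthand", {
  expect_identical(tokenize("He is depressed."), c("He", "is", "depressed", "."))
  expect_identical(tokenize(""), character(0))
  expect_true("etoh" %in% tokenize("Pt reports etoh abuse…"))
})

test_that("tokenizer agrees with an independent per-chunk scanner on generated sentences", {
  scan_chunk <- function(chunk) {
    out <- character(0)
    while (nzchar(chunk)) {
      m <- regmatches(chunk, regexpr("^[A-Za-z0-9]+", chunk))
      if (length(m) && nzchar(m)) {
        out <- c(out, m)
        chunk <- substring(chunk, nchar(m) + 1L)
      } else {
        out <- c(out, substring(chunk, 1L, 1L))
        chunk <- substring(chunk, 2L)
      }
    }
    out
  }
  reference_tokenize <- function(text) {
    chunks <- strsplit(text, "[[:space:]]+")[[1]]
    unlist(lapply(chunks[nzchar(chunks)], scan_chunk))
  }
  co <- generate_corpus(generator_config(n_records = 10, seed = 21))
  sentences <- unlist(lapply(co$records, function(r) {
    strsplit(r$raw_text, "\n", fixed = TRUE)[[1]]
  }))
  sentences <- sentences[nzchar(sentences)][1:100]
  for (s in sentences) {
    expect_identical(tokenize(s), reference_tokenize(s))
  }
})

test_that("merged-token refinement splits case and digit boundaries exhaustively", {
  expect_identical(refine_tokens("PsychiatryChief"), c("Psychiatry", "Chief"))
  expect_identical(refine_tokens("depression"), "depression")
  expect_identical(refine_tokens("10mgDaily"), c("10", "mg", "Daily"))
  refined <- refine_tokens(c("aB2cD", "x1y2z", "HISTORY"))
  expect_false(any(grepl("[a-z][A-Z]|[0-9][A-Za-z]", refined)))
  # idempotent
  expect_identical(refine_tokens(refined), refined)
})

test_that("refinement inverts the generator's token fusions", {
  for (s in 1:10) {
    clean <- generate_corpus(generator_config(n_records = 2, seed = 200 + s,
                                              noise = noise_config(0, 0)))
    rec <- clean$records[[1]]
    noisy <- inject_noise(rec, noise_config(merge_rate = 0.6, misspell_rate = 0),
                          seed = s)
    expect_identical(refine_tokens(tokenize(noisy$raw_text)),
                     refine_tokens(tokenize(rec$raw_text)))
  }
})

test_that("QA extraction matches question/answer lines and leaves narrative alone", {
  ex <- extract_qa_pairs("Any suicidal thoughts? : No")
  expect_identical(ex$pairs$question, "Any suicidal thoughts?")
  expect_identical(ex$pairs$answer, "No")

  narrative <- "He sleeps poorly. No other complaints were raised."
  ex2 <- extract_qa_pairs(narrative)
  expect_identical(nrow(ex2$pairs), 0L)
  expect_identical(ex2$residual, narrative)

  two <- "Sleep problems? : Yes\nAppetite loss?: No"
  ex3 <- extract_qa_pairs(two)
  expect_identical(ex3$pairs$short_form, c("Q1", "Q2"))
  expect_identical(ex3$pairs$question, c("Sleep problems?", "Appetite loss?"))
  expect_identical(ex3$pairs$answer, c("Yes", "No"))

  # attribute-value form
  av <- extract_qa_pairs("Sleep quality: poor")
  expect_identical(av$pairs$question, "Sleep quality")
  expect_identical(av$pairs$answer, "poor")

  expect_error(extract_qa_pairs("x", patterns = "no groups here"), "malformed")
})

test_that("QA spans are disjoint, in bounds, and consistent with the text", {
  co <- generate_corpus(generator_config(n_records = 8, seed = 31))
  for (r in co$records) {
    ex <- extract_qa_pairs(r$raw_text)
    p <- ex$pairs
    expect_gt(nrow(p), 0)
    expect_true(all(p$start >= 0 & p$end <= nchar(r$raw_text)))
    ord <- order(p$start)
    expect_true(all(utils::head(p$end[ord], -1) <= utils::tail(p$start[ord], -1)))
    # the question span really contains the question text
    expect_identical(substr(rep(r$raw_text, nrow(p)), p$q_start + 1L, p$q_end),
                     p$question)
  }
})

test_that("question normalisation assigns corpus-global short forms by first appearance", {
  co <- corpus_from_texts(c(
    "Intro one.\nSleep problems? : Yes\nMood swings? : No\n",
    "Intro two.\nSleep problems? : No\n",
    "Intro three.\nNew worry? : Uncertain\n"
  ), labels = c("MILD", "MILD", "SEVERE"))
  tok <- normalise_questions(preprocess_corpus(co, spell = FALSE))
  qmap <- attr(tok, "question_map")
  expect_identical(unname(qmap[c("Sleep problems?", "Mood swings?", "New worry?")]),
                   c("Q1", "Q2", "Q3"))
  # the shared question gets the same token in both records
  expect_true("Q1" %in% tok$records[[1]]$tokens)
  expect_true("Q1" %in% tok$records[[2]]$tokens)
  expect_false("Sleep" %in% tok$records[[2]]$tokens)
  expect_true(isTRUE(attr(tok, "normalised")))

  # record with three distinct questions and an empty prior mapping
  co3 <- corpus_from_texts(
    "A? : Yes\nB? : No\nC? : None\n")
  tok3 <- normalise_questions(preprocess_corpus(co3, spell = FALSE))
  expect_identical(tok3$records[[1]]$qa_pairs$short_form, c("Q1", "Q2", "Q3"))

  # no QA pairs: unchanged tokens
  plain <- corpus_from_texts("Just narrative text here.")
  tokp <- preprocess_corpus(plain, spell = FALSE)
  expect_identical(normalise_questions(tokp)$records[[1]]$tokens,
                   tokp$records[[1]]$tokens)
})

test_that("normalisation never grows the corpus vocabulary", {
  for (s in c(11, 12, 13)) {
    co <- generate_corpus(generator_config(n_records = 15, seed = s))
    tok <- preprocess_corpus(co)
    tokn <- normalise_questions(tok)
    vocab_size <- function(t) {
      length(unique(unlist(lapply(t$records, `[[`, "tokens"))))
    }
    expect_lte(vocab_size(tokn), vocab_size(tok))
  }
})

test_that("the question map can be written as a TSV audit file", {
  co <- generate_corpus(generator_config(n_records = 3, seed = 2))
  tok <- normalise_questions(preprocess_corpus(co))
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_question_map(tok, path)
  back <- utils::read.delim(path, colClasses = "character")
  expect_identical(back$short_form, df$short_form)
  expect_error(write_question_map(preprocess_corpus(co), path), "normalis")
})
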
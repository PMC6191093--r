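# Bundled lexical material for the synthetic-record generator.
#
# Design: each severity class owns a disjoint cue lexicon; ordinally adjacent
# classes leak into each other at generation time (adjacent_share), which is
# what reproduces the adjacent-class confusion structure of real severity
# annotations. The shared background vocabulary is drawn from a Zipf
# distribution and carries no class signal. Several template questions embed
# cue tokens verbatim ("mild", "severe", "crisis", ...) — exactly the
# confound that makes question normalisation matter: unnormalised, those
# tokens occur in every record regardless of class and dilute the narrative
# cue signal.

.sev_cue_lexicons <- list(
  ABSENT   = c("euthymic", "asymptomatic", "remission", "wellness",
               "resilient", "thriving", "untroubled", "contented"),
  MILD     = c("mild", "occasional", "intermittent", "manageable",
               "transient", "slight", "infrequent", "subclinical"),
  MODERATE = c("moderate", "persistent", "recurrent", "escalating",
               "impairing", "distressing", "frequent", "disruptive"),
  SEVERE   = c("severe", "hospitalisation", "suicidal", "crisis",
               "psychosis", "incapacitating", "emergency", "relentless")
)

.sev_background_vocab <- c(
  "patient", "reports", "states", "notes", "feels", "sleep", "mood",
  "energy", "work", "family", "history", "weekly", "therapy", "session",
  "clinic", "visit", "review", "plan", "goals", "support", "partner",
  "children", "stress", "daily", "routine", "exercise", "walking", "diet",
  "coffee", "morning", "evening", "night", "week", "month", "year",
  "since", "started", "continues", "describes", "mentions", "treatment",
  "home", "school", "job", "shift", "manager", "colleagues", "friends",
  "social", "events", "holiday", "travel", "garden", "cooking", "music",
  "games", "phone", "calls", "neighbour", "church", "volunteering",
  "finances", "budget", "rent", "commute", "driving", "weather", "seasons",
  "pets", "dog", "cat", "appetite", "meals", "breakfast", "dinner",
  "weekend", "brother", "sister", "mother", "father"
)

# Short capitalised / dosage phrases woven into narrative sentences; they are
# the natural fusion sites for the merged-token noise model ("per Dr Hale"
# can fuse to "perDr" / "DrHale", "20 mg" to "20mg").
.sev_phrase_bank <- list(
  c("per", "Dr", "Hale"),
  c("at", "Mercy", "Clinic"),
  c("on", "Prozac", "20", "mg"),
  c("taking", "Zoloft", "50", "mg", "daily"),
  c("with", "Nurse", "Okafor")
)

# polarity: "symptom" = Yes grows with severity; "coping" = Yes shrinks.
.sev_question_bank <- data.frame(
  question = c(
    "Would you describe your current symptoms as mild moderate or severe overall?",
    "Have you had any thoughts of suicide or of harming yourself this fortnight?",
    "Do you feel able to cope with everyday housework and errands?",
    "Is there persistent worry or a recurrent sense of crisis in your life?",
    "Any trouble falling asleep or staying asleep through the night lately?",
    "Has your appetite changed or your weight shifted noticeably this season?",
    "Do occasional cravings for alcohol or other substances interfere with plans?",
    "Would friends say your interest in hobbies has diminished lately?",
    "Have you required an emergency visit or hospitalisation in the past year?",
    "Do you take prescribed tablets each day and attend follow ups reliably?",
    "Is concentration at work or while reading harder than it used to be?",
    "Do swings between elation and sadness disrupt your week significantly?"
  ),
  polarity = c("symptom", "symptom", "coping", "symptom", "symptom", "symptom",
               "symptom", "symptom", "symptom", "coping", "symptom", "symptom"),
  stringsAsFactors = FALSE
)

.sev_answers <- c("Yes", "No", "None", "Uncertain")

# P(answer | class) for symptom-polarity questions, rows = classes 1..4.
.sev_answer_profile <- matrix(
  c(0.05, 0.80, 0.10, 0.05,
    0.35, 0.45, 0.10, 0.10,
    0.65, 0.20, 0.05, 0.10,
    0.92, 0.03, 0.01, 0.04),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("ABSENT", "MILD", "MODERATE", "SEVERE"), .sev_answers)
)

.sev_attribute_bank <- list(
  "Current medication" = c("sertraline 50 mg daily", "fluoxetine 20 mg daily",
                           "none reported", "olanzapine 5 mg nightly"),
  "Sleep quality"      = c("poor", "fair", "good", "variable"),
  "Employment status"  = c("employed", "unemployed", "part time", "retired"),
  "Lives with"         = c("family", "alone", "partner", "roommates"),
  "Tobacco use"        = c("no current use", "former smoker", "daily smoker",
                           "social smoker")
)
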
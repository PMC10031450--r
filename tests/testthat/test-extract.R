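pairs_for <- function(text) {
  sents <- analyze_text(text, LEX)
  meds <- match_entities(sents, text, LEX$medication)
  find_quantity_unit_pairs(sents[[1]],
                           LEX$unit,
                           meds[meds$sentence_index == 0L, , drop = FALSE])
}

test_that("rule Q1 pairs a nummod quantity with its unit head", {
  p <- pairs_for("Started gabapentin at a rate of 2.6 ml.")
  expect_equal(nrow(p), 1)
  expect_equal(p$quantity, 2.6)
  expect_equal(p$unit_canonical, "milliliter")
})

test_that("rule Q2 yields a unitless quantity next to a medication", {
  p <- pairs_for("Gave Alex 2 Benadryl this morning.")
  expect_equal(nrow(p), 1)
  expect_equal(p$quantity, 2)
  expect_true(is.na(p$unit_index))
})

test_that("clock times and sentences without numbers yield no pairs", {
  expect_equal(nrow(pairs_for("Gave Benadryl at 6:00 am.")), 0)
  expect_equal(nrow(pairs_for("Gave Benadryl with water.")), 0)
})

test_that("ranges take their first number", {
  p <- pairs_for("Gave 1-2 tablets of Tylenol.")
  expect_equal(p$quantity, 1)
  expect_equal(p$unit_canonical, "tablet")
})

test_that("taper sentences enumerate one instance per rate in text order", {
  res <- extract_note(gabapentin_note(), LEX)
  qty <- vapply(res$medication_instances, function(m) m$quantity, numeric(1))
  expect_equal(qty, c(2.6, 2, 1.6, 0.6))
  expect_true(all(vapply(res$medication_instances,
                         function(m) m$unit$canonical, character(1)) ==
                    "milliliter"))
  expect_true(all(vapply(res$medication_instances,
                         function(m) m$medication$canonical, character(1)) ==
                    "Gabapentin"))
  # "Yesterday" resolves against the authorship date for every instance
  expect_equal(res$medication_instances[[1]]$when$date,
               note_date(gabapentin_note()) - 1)
})

test_that("a medication with no numbers still yields one bare instance", {
  res <- extract_note(quick_note("Took melatonin before bed."), LEX)
  expect_length(res$medication_instances, 1)
  expect_null(res$medication_instances[[1]]$quantity)
  expect_null(res$medication_instances[[1]]$unit)
  # falls back to the note date with provenance
  expect_equal(res$medication_instances[[1]]$when$provenance,
               "note-date-default")
  expect_equal(res$medication_instances[[1]]$when$date,
               as.Date("2020-11-05"))
})

test_that("the antihistamine worked example extracts dose and time", {
  res <- extract_note(benadryl_note(), LEX)
  expect_gte(length(res$medication_instances), 1)
  mi <- res$medication_instances[[1]]
  expect_equal(mi$medication$canonical, "Diphenhydramine")
  expect_equal(mi$quantity, 2)
  expect_null(mi$unit)
  expect_equal(mi$when$time_of_day, "06:00")
})

test_that("symptom-only worked example yields mentions and no instances", {
  res <- extract_note(sample_notes()[[1]], LEX)
  expect_length(res$medication_instances, 0)
  expect_gte(length(res$symptom_mentions), 1)
  expect_equal(res$category, "symptom_only")
  # negation is not modelled: "no fever" still asserts a fever mention
  canons <- vapply(res$symptom_mentions, function(s) s$symptom$canonical,
                   character(1))
  expect_true("Fever" %in% canons)
  expect_true(all(vapply(res$symptom_mentions, function(s) s$polarity,
                         character(1)) == "asserted"))
})

test_that("every symptom occurrence counts, across sentences", {
  res <- extract_note(quick_note("Has a fever tonight. Fever was high."),
                      LEX)
  canons <- vapply(res$symptom_mentions, function(s) s$symptom$canonical,
                   character(1))
  expect_equal(canons, c("Fever", "Fever"))
})

test_that("contentless notes never throw and come back empty", {
  res <- extract_note(quick_note("ok today"), LEX)
  expect_equal(res$category, "none")
  expect_length(res$medication_instances, 0)
})

test_that("unit-present implies quantity-present on noisy fuzzed corpora", {
  corpus <- generate_corpus(generator_config(n_notes = 100, seed = 31,
                                             asr_error_note_rate = 0.5),
                            LEX)
  preds <- extract_corpus(corpus$notes, LEX)
  for (p in preds) {
    meds <- match_entities(analyze_text(
      corpus$notes[[match(p$note_id, vapply(corpus$notes,
                                            function(n) n$note_id,
                                            character(1)))]]$text, LEX),
      corpus$notes[[match(p$note_id, vapply(corpus$notes,
                                            function(n) n$note_id,
                                            character(1)))]]$text,
      LEX$medication)
    expect_gte(length(p$medication_instances), length(unique(meds$start)))
    for (mi in p$medication_instances) {
      if (!is.null(mi$unit)) expect_false(is.null(mi$quantity))
      if (!is.null(mi$quantity)) expect_gt(mi$quantity, 0)
    }
  }
})

test_that("shuffling note order never changes per-note results", {
  corpus <- generate_corpus(generator_config(n_notes = 30, seed = 41), LEX)
  preds <- extract_corpus(corpus$notes, LEX)
  set.seed(1)
  perm <- sample(30)
  preds_perm <- extract_corpus(corpus$notes[perm], LEX)
  expect_equal(preds_perm, preds[perm])
})

test_that("ambiguous medication/symptom terms resolve to medication", {
  # "water" is only a medication entry; craft an overlap via a temp lexicon
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("fever\tFever Brand\tRX:9999", path)
  lex2 <- LEX
  lex2$medication <- load_lexicon(path, "medication")
  res <- extract_note(quick_note("Has a fever."), lex2)
  expect_length(res$medication_instances, 1)
  expect_length(res$symptom_mentions, 0)
})
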
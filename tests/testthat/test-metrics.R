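counts_of <- function(counts, comp) {
  as.list(counts[counts$component == comp, c("tp", "fp", "fn")])
}

test_that("prf computes P, R and harmonic F1 with the 0/0 convention", {
  expect_equal(prf(5, 5, 5), c(precision = 0.5, recall = 0.5, f1 = 0.5))
  expect_equal(suppressMessages(prf(0, 0, 0)),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(suppressMessages(prf(0, 3, 0)),
               c(precision = 0, recall = 0, f1 = 0))
  out <- prf(52, 11, 7)
  expect_equal(unname(out["precision"]), 52 / 63)
  expect_equal(unname(out["recall"]), 52 / 59)
  expect_equal(unname(out["f1"]),
               2 * (52 / 63) * (52 / 59) / ((52 / 63) + (52 / 59)))
  # F1 lies between P and R whenever defined
  expect_true(out["f1"] >= min(out[1:2]) && out["f1"] <= max(out[1:2]))
})

test_that("an identical instance scores tp on every component", {
  pred <- mk_pred("n1", list(mk_pred_instance("Gabapentin", 2.6,
                                              "milliliter",
                                              date = as.Date("2020-11-04"))))
  gold <- pghd_gold("n1", list(mk_gold_instance("Gabapentin", 2.6,
                                                "milliliter",
                                                date = as.Date("2020-11-04"))))
  counts <- match_note(pred, gold)
  expect_equal(counts_of(counts, "medication_instance"),
               list(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(counts_of(counts, "medication"),
               list(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(counts_of(counts, "unit"), list(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(counts_of(counts, "quantity"),
               list(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(counts_of(counts, "date"), list(tp = 1L, fp = 0L, fn = 0L))
})

test_that("a wrong quantity fails the instance but not the name", {
  pred <- mk_pred("n1", list(mk_pred_instance("Gabapentin", 3)))
  gold <- pghd_gold("n1", list(mk_gold_instance("Gabapentin", 2.6)))
  counts <- match_note(pred, gold)
  expect_equal(counts_of(counts, "medication"),
               list(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(counts_of(counts, "quantity"),
               list(tp = 0L, fp = 1L, fn = 1L))
  expect_equal(counts_of(counts, "medication_instance"),
               list(tp = 0L, fp = 1L, fn = 1L))
})

test_that("a spurious extraction is a medication false positive", {
  pred <- mk_pred("n1", list(mk_pred_instance("Water")))
  gold <- pghd_gold("n1", list())
  counts <- match_note(pred, gold)
  expect_equal(counts_of(counts, "medication"),
               list(tp = 0L, fp = 1L, fn = 0L))
  # and a missed gold instance is a false negative likewise
  counts2 <- match_note(mk_pred("n1"),
                        pghd_gold("n1", list(mk_gold_instance("Gabapentin",
                                                              2.6, "milliliter"))))
  expect_equal(counts_of(counts2, "medication"),
               list(tp = 0L, fp = 0L, fn = 1L))
  expect_equal(counts_of(counts2, "unit"), list(tp = 0L, fp = 0L, fn = 1L))
})

test_that("symptoms score as per-note multisets", {
  pred <- mk_pred("n1", symptoms = c("Fever", "Fever", "Cough"))
  gold <- pghd_gold("n1", gold_symptoms = c("Fever", "Rash"))
  counts <- match_note(pred, gold)
  expect_equal(counts_of(counts, "symptom"),
               list(tp = 1L, fp = 2L, fn = 1L))
})

test_that("note_id mismatch is a hard error", {
  expect_error(match_note(mk_pred("a"), pghd_gold("b")), "mismatch")
})

test_that("instance_correct demands all presented subcomponents", {
  g_full <- mk_gold_instance("Diphenhydramine", 2, time_of_day = "06:00")
  p_full <- mk_pred_instance("Diphenhydramine", 2, time_of_day = "06:00")
  expect_true(instance_correct(p_full, g_full))
  # missed unit
  expect_false(instance_correct(
    mk_pred_instance("Gabapentin", 2.6),
    mk_gold_instance("Gabapentin", 2.6, "milliliter")))
  # spurious subcomponent
  expect_false(instance_correct(mk_pred_instance("Gabapentin", 5),
                                mk_gold_instance("Gabapentin")))
})

test_that("instance_correct is reflexive over generated gold", {
  corpus <- generate_corpus(generator_config(n_notes = 40, seed = 13), LEX)
  preds <- extract_corpus(corpus$notes, LEX)
  for (p in preds) for (mi in p$medication_instances) {
    gi <- list(medication = mi$medication$canonical,
               quantity = mi$quantity,
               unit = if (is.null(mi$unit)) NULL else mi$unit$canonical,
               when = if (is.null(mi$when) || mi$when$status != "resolved")
                 NULL else list(date = mi$when$date,
                                time_of_day = mi$when$time_of_day))
    expect_true(instance_correct(mi, gi))
  }
})

test_that("an identity corpus evaluates to 1.0 everywhere", {
  corpus <- generate_corpus(generator_config(n_notes = 20, seed = 19,
                                             asr_error_note_rate = 0), LEX)
  preds <- extract_corpus(corpus$notes, LEX)
  rep <- evaluate_corpus(preds, corpus$gold)$report
  expect_true(all(rep$precision == 1))
  expect_true(all(rep$recall == 1))
  expect_true(all(rep$f1 == 1))
  # notes_n / instances_n come from gold
  n_gold_inst <- sum(lengths(lapply(corpus$gold, `[[`, "gold_instances")))
  expect_equal(rep$instances_n[rep$component == "medication"], n_gold_inst)
})

test_that("empty predictions on non-empty gold score zero by convention", {
  corpus <- generate_corpus(generator_config(n_notes = 10, seed = 29,
                                             asr_error_note_rate = 0), LEX)
  empty <- lapply(corpus$notes, function(n) pghd_extraction(n$note_id))
  rep <- suppressMessages(evaluate_corpus(empty, corpus$gold))$report
  expect_true(all(rep$precision == 0))
  expect_true(all(rep$recall == 0))
})

test_that("evaluation is invariant to note order and count-level splits", {
  corpus <- generate_corpus(generator_config(n_notes = 24, seed = 37), LEX)
  preds <- extract_corpus(corpus$notes, LEX)
  m_all <- evaluate_corpus(preds, corpus$gold)
  set.seed(2)
  perm <- sample(24)
  m_perm <- evaluate_corpus(preds[perm], corpus$gold[perm])
  expect_equal(m_perm$report, m_all$report)
  # summing counts over two halves reproduces the whole
  m1 <- evaluate_corpus(preds[1:12], corpus$gold[1:12])$counts
  m2 <- evaluate_corpus(preds[13:24], corpus$gold[13:24])$counts
  expect_equal(m1$tp + m2$tp, m_all$counts$tp)
  expect_equal(m1$fp + m2$fp, m_all$counts$fp)
  expect_equal(m1$fn + m2$fn, m_all$counts$fn)
})

test_that("the TSV report has the documented columns", {
  corpus <- generate_corpus(generator_config(n_notes = 8, seed = 43), LEX)
  m <- evaluate_corpus(extract_corpus(corpus$notes, LEX), corpus$gold)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(m, path)
  tab <- utils::read.delim(path)
  expect_equal(names(tab), c("component", "precision", "recall", "f1",
                             "notes_n", "instances_n"))
  expect_equal(nrow(tab), 6)
})
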
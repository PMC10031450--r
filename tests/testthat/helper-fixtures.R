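# Shared fixtures: the packaged lexicons, the worked-example notes, and
# small constructors used across test files.

LEX <- default_lexicons()

sample_notes <- function() {
  read_notes(system.file("extdata", "sample_notes.jsonl", package = "pghdex"))
}

# The two dose-bearing worked-example notes.
benadryl_note <- function() sample_notes()[[3]]
gabapentin_note <- function() sample_notes()[[4]]

quick_note <- function(text, authored_at = "2020-11-05T10:00:00",
                       note_id = "t1") {
  pghd_note(note_id = note_id, text = text, authored_at = authored_at,
            modality = "typed")
}

# A hand-built medication instance for metric tests (name-anchored, like
# the gold schema).
mk_pred_instance <- function(canonical, quantity = NULL, unit = NULL,
                             date = NULL, time_of_day = NULL) {
  med <- pghdex:::new_mention(0L, 1L, canonical, "medication", "RX:0",
                              canonical, 0L, 0L)
  when <- if (is.null(date) && is.null(time_of_day)) NULL else
    pghdex:::new_when(raw = "x", date = date, time_of_day = time_of_day,
                      status = "resolved")
  unit_obj <- if (is.null(unit)) NULL else
    list(surface = unit, canonical = unit, concept_id = "UCUM:x")
  pghdex:::new_med_instance(med, quantity = quantity, unit = unit_obj,
                            when = when)
}

mk_gold_instance <- function(canonical, quantity = NULL, unit = NULL,
                             date = NULL, time_of_day = NULL) {
  when <- if (is.null(date) && is.null(time_of_day)) NULL else
    list(date = date, time_of_day = time_of_day)
  out <- list(medication = canonical)
  if (!is.null(quantity)) out$quantity <- quantity
  if (!is.null(unit)) out$unit <- unit
  if (!is.null(when)) out$when <- when
  out
}

mk_pred <- function(note_id, instances = list(), symptoms = character()) {
  sym <- lapply(seq_along(symptoms), function(i) {
    pghdex:::new_symptom_mention(
      pghdex:::new_mention(0L, 1L, symptoms[i], "symptom", "SCT:0",
                           symptoms[i], 0L, 0L))
  })
  pghd_extraction(note_id, instances, sym)
}

serialize_corpus <- function(corpus) {
  paste(vapply(corpus$notes, function(n)
    as.character(jsonlite::toJSON(unclass(n), auto_unbox = TRUE,
                                  null = "null")), character(1)),
    vapply(corpus$gold, function(g)
      as.character(jsonlite::toJSON(pghdex:::gold_to_json(g),
                                    auto_unbox = TRUE, null = "null")),
      character(1)),
    collapse = "\n")
}
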
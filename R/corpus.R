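# Core data model: notes, extraction results, gold annotations, JSONL I/O.
#
# Interchange is JSON Lines (one record per line, UTF-8). Character offsets
# are 0-based half-open [start, end) over code points throughout.

NOTE_FIELDS <- c("note_id", "text", "authored_at", "modality", "author_id")
MODALITIES <- c("voice_transcript", "typed")
CATEGORIES <- c("medication_only", "symptom_only", "both", "none")

#' Construct a patient note
#'
#' A note is one free-text entry of patient-generated health data (PGHD):
#' a short diary-style record authored by a patient or caregiver, either
#' typed or transcribed from voice.
#'
#' @param note_id Opaque identifier string.
#' @param text Free text; must be non-empty after whitespace stripping.
#' @param authored_at Authorship timestamp, ISO-8601 (`"2020-11-05"` or
#'   `"2020-11-05T08:30:00"`); relative dates in the text resolve against it.
#' @param modality `"voice_transcript"` or `"typed"`.
#' @param author_id Optional author identifier.
#' @param extra Named list of additional fields, preserved opaquely on
#'   read and echoed on write.
#' @return An object of class `pghd_note`.
#' @export
pghd_note <- function(note_id, text, authored_at, modality = "typed",
                      author_id = NULL, extra = list()) {
  stopifnot(is_scalar_chr(note_id), is_scalar_chr(text),
            is_scalar_chr(authored_at))
  if (!nzchar(trimws(text))) stop("note text is empty", call. = FALSE)
  if (is.na(parse_note_date(authored_at)))
    stop("authored_at does not parse to a calendar date: ", authored_at,
         call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  structure(list(note_id = note_id, text = text, authored_at = authored_at,
                 modality = modality, author_id = author_id, extra = extra),
            class = "pghd_note")
}

parse_note_date <- function(authored_at) {
  as.Date(substr(authored_at, 1L, 10L), format = "%Y-%m-%d")
}

#' Authorship date of a note
#'
#' @param note A `pghd_note`.
#' @return A `Date`; the calendar date relative temporal expressions
#'   ("yesterday", "2 days ago") are resolved against.
#' @export
note_date <- function(note) parse_note_date(note$authored_at)

#' @export
print.pghd_note <- function(x, ...) {
  cat(sprintf("<pghd_note %s> %s [%s]\n", x$note_id, x$authored_at,
              x$modality))
  cat(" ", substr(x$text, 1, 70),
      if (nchar(x$text) > 70) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Read notes from a JSONL file
#'
#' One JSON object per line with keys `note_id`, `text`, `authored_at`,
#' `modality`, `author_id`. Malformed lines and lines missing a required
#' field are skipped with a warning naming the line number; unknown fields
#' are kept on the note and round-trip through [write_notes()].
#'
#' @param path Path to a JSONL file.
#' @return List of `pghd_note`, in file order. Raises an error if no line
#'   yields a valid note.
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  notes <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj) || !is.list(obj)) {
      warning(sprintf("line %d: malformed JSON, skipped", i), call. = FALSE)
      next
    }
    note <- tryCatch(note_from_json(obj), error = function(e) {
      warning(sprintf("line %d: %s, skipped", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(note)) notes[[length(notes) + 1L]] <- note
  }
  if (length(notes) == 0L)
    stop("no valid notes in ", path, call. = FALSE)
  notes
}

note_from_json <- function(obj) {
  for (f in c("note_id", "text", "authored_at")) {
    if (is.null(obj[[f]])) stop("missing required field '", f, "'",
                                call. = FALSE)
  }
  extra <- obj[setdiff(names(obj), NOTE_FIELDS)]
  if (length(extra) == 0L) extra <- list()
  pghd_note(note_id = as.character(obj$note_id),
            text = as.character(obj$text),
            authored_at = as.character(obj$authored_at),
            modality = if (is.null(obj$modality)) "typed"
                       else as.character(obj$modality),
            author_id = if (is.null(obj$author_id)) NULL
                        else as.character(obj$author_id),
            extra = extra)
}

#' Write notes to a JSONL file
#'
#' @param notes List of `pghd_note`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  lines <- vapply(notes, function(n) {
    obj <- c(list(note_id = n$note_id, text = n$text,
                  authored_at = n$authored_at, modality = n$modality),
             if (!is.null(n$author_id)) list(author_id = n$author_id),
             n$extra)
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- extraction results -----------------------------------------------------

new_mention <- function(start, end, surface, vocabulary, concept_id,
                        canonical, sentence_index, head_token_index) {
  list(start = as.integer(start), end = as.integer(end),
       surface = as.character(surface), vocabulary = as.character(vocabulary),
       concept_id = as.character(concept_id),
       canonical = as.character(canonical),
       sentence_index = as.integer(sentence_index),
       head_token_index = as.integer(head_token_index))
}

new_med_instance <- function(medication, quantity = NULL, unit = NULL,
                             when = NULL, evidence_sentence = 0L) {
  if (!is.null(unit) && is.null(quantity))
    stop("a unit never floats without a quantity", call. = FALSE)
  if (!is.null(quantity) && quantity <= 0)
    stop("quantity must be > 0", call. = FALSE)
  structure(list(medication = medication,
                 quantity = if (is.null(quantity)) NULL else as.numeric(quantity),
                 unit = unit, when = when,
                 evidence_sentence = as.integer(evidence_sentence)),
            class = "med_instance")
}

new_symptom_mention <- function(symptom, evidence_sentence = 0L) {
  # Polarity is fixed: negation is out of scope, so "no fever" still yields
  # an asserted fever mention.
  structure(list(symptom = symptom, polarity = "asserted",
                 evidence_sentence = as.integer(evidence_sentence)),
            class = "symptom_mention")
}

#' Construct an extraction result
#'
#' @param note_id Note identifier the result belongs to.
#' @param medication_instances List of medication instances in text order.
#' @param symptom_mentions List of symptom mentions in text order.
#' @return An object of class `pghd_extraction`; its `category` field is
#'   derived from the two lists via [categorize_note()].
#' @export
pghd_extraction <- function(note_id, medication_instances = list(),
                            symptom_mentions = list()) {
  res <- structure(list(note_id = note_id,
                        medication_instances = medication_instances,
                        symptom_mentions = symptom_mentions,
                        category = NA_character_),
                   class = "pghd_extraction")
  res$category <- categorize_note(res)
  res
}

#' Categorize a note by extraction content
#'
#' The four-way split used to characterize a PGHD corpus: a note is
#' `medication_only`, `symptom_only`, `both`, or `none` purely as a function
#' of whether the medication-instance and symptom-mention lists are empty.
#'
#' @param result A `pghd_extraction`.
#' @return One of `"medication_only"`, `"symptom_only"`, `"both"`, `"none"`.
#' @export
categorize_note <- function(result) {
  n_med <- length(result$medication_instances)
  n_sym <- length(result$symptom_mentions)
  if (n_med > 0L && n_sym == 0L) "medication_only"
  else if (n_med == 0L && n_sym > 0L) "symptom_only"
  else if (n_med > 0L && n_sym > 0L) "both"
  else "none"
}

#' @export
print.pghd_extraction <- function(x, ...) {
  cat(sprintf("<pghd_extraction %s> category=%s, %d medication instance(s), %d symptom mention(s)\n",
              x$note_id, x$category, length(x$medication_instances),
              length(x$symptom_mentions)))
  for (mi in x$medication_instances) {
    cat(sprintf("  med %-24s qty=%-6s unit=%-12s when=%s\n",
                mi$medication$canonical,
                if (is.null(mi$quantity)) "-" else format(mi$quantity),
                if (is.null(mi$unit)) "-" else mi$unit$canonical,
                format_when(mi$when)))
  }
  for (sm in x$symptom_mentions)
    cat(sprintf("  sym %s\n", sm$symptom$canonical))
  invisible(x)
}

format_when <- function(w) {
  if (is.null(w)) return("-")
  if (w$status == "unresolved_phrasal") return(sprintf("?(%s)", w$raw))
  paste0(if (!is.null(w$date)) format(w$date) else "",
         if (!is.null(w$date) && !is.null(w$time_of_day)) " " else "",
         if (!is.null(w$time_of_day)) w$time_of_day else "")
}

when_to_json <- function(w) {
  if (is.null(w)) return(NULL)
  obj <- list(raw = w$raw)
  if (!is.null(w$date)) obj$date <- format(w$date, "%Y-%m-%d")
  if (!is.null(w$time_of_day)) obj$time_of_day <- w$time_of_day
  obj$status <- w$status
  if (!is.null(w$provenance)) obj$provenance <- w$provenance
  if (isTRUE(w$ambiguous_meridiem)) obj$ambiguous_meridiem <- TRUE
  obj
}

when_from_json <- function(obj) {
  if (is.null(obj)) return(NULL)
  new_when(raw = as.character(obj$raw),
           date = if (is.null(obj$date)) NULL else as.Date(obj$date),
           time_of_day = if (is.null(obj$time_of_day)) NULL
                         else as.character(obj$time_of_day),
           status = as.character(obj$status),
           provenance = if (is.null(obj$provenance)) NULL
                        else as.character(obj$provenance),
           ambiguous_meridiem = isTRUE(obj$ambiguous_meridiem))
}

mention_to_json <- function(m) m

mention_from_json <- function(obj) {
  new_mention(obj$start, obj$end, obj$surface, obj$vocabulary,
              obj$concept_id, obj$canonical, obj$sentence_index,
              obj$head_token_index)
}

extraction_to_json <- function(res) {
  list(note_id = res$note_id,
       category = res$category,
       medication_instances = lapply(res$medication_instances, function(mi) {
         obj <- list(medication = mention_to_json(mi$medication))
         if (!is.null(mi$quantity)) obj$quantity <- mi$quantity
         if (!is.null(mi$unit)) obj$unit <- mi$unit
         if (!is.null(mi$when)) obj$when <- when_to_json(mi$when)
         obj$evidence_sentence <- mi$evidence_sentence
         obj
       }),
       symptom_mentions = lapply(res$symptom_mentions, function(sm) {
         list(symptom = mention_to_json(sm$symptom), polarity = sm$polarity,
              evidence_sentence = sm$evidence_sentence)
       }))
}

extraction_from_json <- function(obj) {
  meds <- lapply(obj$medication_instances, function(mi) {
    new_med_instance(
      medication = mention_from_json(mi$medication),
      quantity = if (is.null(mi$quantity)) NULL else as.numeric(mi$quantity),
      unit = if (is.null(mi$unit))
               NULL
             else
               list(surface = as.character(mi$unit$surface),
                    canonical = as.character(mi$unit$canonical),
                    concept_id = as.character(mi$unit$concept_id)),
      when = when_from_json(mi$when),
      evidence_sentence = mi$evidence_sentence)
  })
  syms <- lapply(obj$symptom_mentions, function(sm) {
    new_symptom_mention(symptom = mention_from_json(sm$symptom),
                        evidence_sentence = sm$evidence_sentence)
  })
  pghd_extraction(as.character(obj$note_id), meds, syms)
}

#' Write extraction results to JSONL
#'
#' One JSON object per note: `note_id`, `category`, `medication_instances`
#' (each with `medication` mention, optional `quantity`, `unit`, `when`),
#' `symptom_mentions`. Re-reading with [read_extractions()] reproduces an
#' equal object graph.
#'
#' @param results List of `pghd_extraction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extractions <- function(results, path) {
  lines <- vapply(results, function(r) {
    as.character(jsonlite::toJSON(extraction_to_json(r), auto_unbox = TRUE,
                                  digits = NA, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read extraction results from JSONL
#'
#' @param path Path written by [write_extractions()].
#' @return List of `pghd_extraction`.
#' @export
read_extractions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line)
    extraction_from_json(jsonlite::fromJSON(line, simplifyVector = FALSE)))
}

# ---- gold annotations -------------------------------------------------------

#' Construct a gold annotation
#'
#' Reference annotations for one note, name-anchored (not span-anchored):
#' each gold instance carries a canonical medication name and whichever of
#' quantity, unit and when are stated; gold symptoms are canonical names
#' with multiplicity.
#'
#' @param note_id Note identifier.
#' @param gold_instances List of lists with fields `medication` (canonical
#'   name), optional `quantity` (number), `unit` (canonical name), `when`
#'   (list with optional `date`, `time_of_day`).
#' @param gold_symptoms Character vector of canonical symptom names,
#'   repeated mentions repeated.
#' @return An object of class `pghd_gold`.
#' @export
pghd_gold <- function(note_id, gold_instances = list(),
                      gold_symptoms = character()) {
  structure(list(note_id = note_id, gold_instances = gold_instances,
                 gold_symptoms = as.character(gold_symptoms)),
            class = "pghd_gold")
}

gold_to_json <- function(g) {
  list(note_id = g$note_id,
       gold_instances = lapply(g$gold_instances, function(gi) {
         obj <- list(medication = gi$medication)
         if (!is.null(gi$quantity)) obj$quantity <- gi$quantity
         if (!is.null(gi$unit)) obj$unit <- gi$unit
         if (!is.null(gi$when)) {
           w <- list()
           if (!is.null(gi$when$date)) w$date <- format(gi$when$date, "%Y-%m-%d")
           if (!is.null(gi$when$time_of_day)) w$time_of_day <- gi$when$time_of_day
           obj$when <- w
         }
         obj
       }),
       gold_symptoms = as.list(g$gold_symptoms))
}

gold_from_json <- function(obj) {
  pghd_gold(
    note_id = as.character(obj$note_id),
    gold_instances = lapply(obj$gold_instances, function(gi) {
      out <- list(medication = as.character(gi$medication))
      if (!is.null(gi$quantity)) out$quantity <- as.numeric(gi$quantity)
      if (!is.null(gi$unit)) out$unit <- as.character(gi$unit)
      if (!is.null(gi$when)) {
        w <- list()
        if (!is.null(gi$when$date)) w$date <- as.Date(gi$when$date)
        if (!is.null(gi$when$time_of_day))
          w$time_of_day <- as.character(gi$when$time_of_day)
        out$when <- w
      }
      out
    }),
    gold_symptoms = unlist(lapply(obj$gold_symptoms, as.character)) %||%
      character())
}

#' Write gold annotations to JSONL
#' @param golds List of `pghd_gold`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(golds, path) {
  lines <- vapply(golds, function(g) {
    as.character(jsonlite::toJSON(gold_to_json(g), auto_unbox = TRUE,
                                  digits = NA, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read gold annotations from JSONL
#' @param path Path written by [write_gold()].
#' @return List of `pghd_gold`.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line)
    gold_from_json(jsonlite::fromJSON(line, simplifyVector = FALSE)))
}
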
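# Core extraction: assemble medication instances (name + quantity + unit +
# date/time) and symptom mentions from entity mentions, dependency arcs and
# POS tags. All rules operate within one sentence; quantity/unit relations
# never cross sentence boundaries (cross-sentence splits are a known,
# accepted failure mode of diary-style notes).

is_clock_token <- function(surface) grepl(CLOCK_RE, surface)
is_date_token <- function(surface) grepl(DATE_RE, surface)

# "1-2" style ranges take the first number; plain decimals parse directly.
quantity_value <- function(surface) {
  as.numeric(sub("-.*$", "", surface))
}

#' Find quantity-unit pairs in a sentence
#'
#' Two rules over the dependency tree and POS tags:
#' * Q1 — a `NUM` token with relation `nummod` whose head is a
#'   unit-lexicon token yields (quantity, unit);
#' * Q2 — a `NUM` token whose head lies inside a medication mention, or
#'   that immediately precedes one, yields (quantity, no unit).
#'
#' Clock-time and date-shaped tokens are reserved for temporal extraction
#' and never become quantities; each `NUM` token is used at most once, with
#' Q1 taking precedence.
#'
#' @param sentence One parsed sentence from [analyze_text()].
#' @param unit_lexicon The unit `pghd_lexicon`.
#' @param med_mentions Mentions from the medication lexicon for this
#'   sentence (data frame, may be empty); consulted by rule Q2.
#' @return Data frame ordered by text position: `qty_index` (0-based token
#'   index), `quantity` (numeric, > 0), `unit_index` (0-based token index or
#'   `NA`), `unit_surface`, `unit_canonical`, `unit_concept_id`.
#' @export
find_quantity_unit_pairs <- function(sentence, unit_lexicon,
                                     med_mentions = NULL) {
  tokens <- sentence$tokens
  n <- nrow(tokens)
  out <- list()
  med_tok <- integer()
  if (!is.null(med_mentions) && nrow(med_mentions) > 0L) {
    for (r in seq_len(nrow(med_mentions))) {
      span <- tokens$start >= med_mentions$start[r] &
        tokens$end <= med_mentions$end[r]
      med_tok <- c(med_tok, tokens$index[span])
    }
  }
  for (i in seq_len(n)) {
    if (tokens$pos[i] != "NUM") next
    surf <- tokens$surface[i]
    if (is_clock_token(surf) || is_date_token(surf)) next
    qty <- quantity_value(surf)
    if (is.na(qty) || qty <= 0) next
    h <- tokens$head[i] + 1L
    # Q1: nummod into a unit-lexicon token.
    if (tokens$dep[i] == "nummod" &&
        !is.null(hit <- lexicon_lookup(unit_lexicon,
                                       normalize_term(tokens$surface[h])))) {
      out[[length(out) + 1L]] <- data.frame(
        qty_index = tokens$index[i], quantity = qty,
        unit_index = tokens$index[h], unit_surface = tokens$surface[h],
        unit_canonical = hit$canonical, unit_concept_id = hit$concept_id,
        stringsAsFactors = FALSE)
      next
    }
    # Q2: head inside a medication mention, or immediately precedes one.
    if ((tokens$index[h] %in% med_tok) ||
        (i < n && tokens$index[i + 1L] %in% med_tok)) {
      out[[length(out) + 1L]] <- data.frame(
        qty_index = tokens$index[i], quantity = qty,
        unit_index = NA_integer_, unit_surface = NA_character_,
        unit_canonical = NA_character_, unit_concept_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(qty_index = integer(), quantity = numeric(),
                      unit_index = integer(), unit_surface = character(),
                      unit_canonical = character(),
                      unit_concept_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Attach quantity-unit pairs to medication mentions
#'
#' Each pair attaches to the medication mention whose head token is closest
#' along the (undirected) dependency path; ties break by smallest character
#' distance, then leftmost mention. A medication with no attached pair
#' yields one bare instance; one with several pairs yields one instance per
#' pair in text order (dose-taper enumeration).
#'
#' @param pairs Output of [find_quantity_unit_pairs()] for one sentence.
#' @param med_mentions Medication mentions in that sentence (data frame).
#' @param sentence The parsed sentence.
#' @param sentence_index 0-based sentence index recorded on the instances.
#' @return List of draft `med_instance` (without `when`, attached later).
#' @export
attach_to_medication <- function(pairs, med_mentions, sentence,
                                 sentence_index = 0L) {
  if (is.null(med_mentions) || nrow(med_mentions) == 0L) return(list())
  tokens <- sentence$tokens
  assigned <- vector("list", nrow(med_mentions))
  if (nrow(pairs) > 0L) {
    for (p in seq_len(nrow(pairs))) {
      best <- NA_integer_; best_key <- NULL
      for (m in seq_len(nrow(med_mentions))) {
        d <- dep_path_distance(tokens, pairs$qty_index[p],
                               med_mentions$head_token_index[m])
        if (is.na(d)) d <- nrow(tokens)  # disconnected: worst path
        cd <- abs(tokens$start[pairs$qty_index[p] + 1L] -
                    med_mentions$start[m])
        key <- c(d, cd, m)
        if (is.null(best_key) ||
            key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2]) ||
            (key[1] == best_key[1] && key[2] == best_key[2] && m < best)) {
          best <- m; best_key <- key
        }
      }
      assigned[[best]] <- c(assigned[[best]], p)
    }
  }
  instances <- list()
  for (m in order(med_mentions$start)) {
    med <- as.list(med_mentions[m, , drop = FALSE])
    med <- new_mention(med$start, med$end, med$surface, med$vocabulary,
                       med$concept_id, med$canonical, sentence_index,
                       med$head_token_index)
    ps <- assigned[[m]]
    if (is.null(ps)) {
      instances[[length(instances) + 1L]] <-
        new_med_instance(med, evidence_sentence = sentence_index)
    } else {
      for (p in ps[order(pairs$qty_index[ps])]) {
        unit <- if (is.na(pairs$unit_index[p])) NULL else
          list(surface = pairs$unit_surface[p],
               canonical = pairs$unit_canonical[p],
               concept_id = pairs$unit_concept_id[p])
        instances[[length(instances) + 1L]] <-
          new_med_instance(med, quantity = pairs$quantity[p], unit = unit,
                           evidence_sentence = sentence_index)
      }
    }
  }
  instances
}

#' Turn symptom mentions into symptom records
#'
#' One record per mention, no deduplication across (or within) sentences:
#' each occurrence counts. Polarity is always `"asserted"` because negation
#' is not handled — "no fever" still yields a fever mention.
#'
#' @param symptom_mentions Data frame of symptom-lexicon mentions.
#' @return List of `symptom_mention` objects in text order.
#' @export
extract_symptoms <- function(symptom_mentions) {
  if (is.null(symptom_mentions) || nrow(symptom_mentions) == 0L)
    return(list())
  ord <- order(symptom_mentions$sentence_index, symptom_mentions$start)
  lapply(ord, function(r) {
    m <- symptom_mentions[r, , drop = FALSE]
    new_symptom_mention(
      new_mention(m$start, m$end, m$surface, m$vocabulary, m$concept_id,
                  m$canonical, m$sentence_index, m$head_token_index),
      evidence_sentence = m$sentence_index)
  })
}

#' Extract medication instances and symptom mentions from one note
#'
#' The full pipeline for a single note: parse (sentences, POS, dependency
#' arcs) → dictionary entity recognition (medication, symptom, unit
#' vocabularies; medication wins ambiguous terms) → quantity/unit pairing →
#' attachment to medications → temporal resolution against the authorship
#' date → symptom records → note categorization. Deterministic under the
#' fallback backend; content never raises (worst case is an empty result of
#' category `"none"`).
#'
#' @param note A `pghd_note`.
#' @param lexicons Named lexicon list from [default_lexicons()].
#' @param backend `"fallback"` or `"pretrained"`.
#' @param date_dialect `"mdy"` or `"dmy"` numeric-date reading.
#' @param stop_terms Optional normalized terms (e.g. patient names) to
#'   exclude from medication matching.
#' @return A `pghd_extraction`.
#' @export
extract_note <- function(note, lexicons, backend = "fallback",
                         date_dialect = "mdy", stop_terms = NULL) {
  stopifnot(inherits(note, "pghd_note"))
  sentences <- analyze_text(note$text, lexicons, backend)
  if (length(sentences) == 0L)
    return(pghd_extraction(note$note_id))
  text <- note$text
  med_all <- match_entities(sentences, text, lexicons$medication,
                            stop_terms = stop_terms)
  blocked <- lapply(seq_along(sentences), function(k) {
    rows <- med_all$sentence_index == (k - 1L)
    if (!any(rows)) return(integer())
    unlist(lapply(which(rows), function(r) {
      tok <- sentences[[k]]$tokens
      tok$index[tok$start >= med_all$start[r] & tok$end <= med_all$end[r]]
    }))
  })
  sym_all <- match_entities(sentences, text, lexicons$symptom,
                            blocked = blocked)
  reference <- note_date(note)
  instances <- list()
  last_when <- NULL
  for (k in seq_along(sentences)) {
    sent <- sentences[[k]]
    meds <- med_all[med_all$sentence_index == (k - 1L), , drop = FALSE]
    pairs <- find_quantity_unit_pairs(sent, lexicons$unit, meds)
    drafts <- attach_to_medication(pairs, meds, sent,
                                   sentence_index = k - 1L)
    spans <- detect_temporal(sent, lexicons$temporal_trigger, text,
                             date_dialect)
    when_k <- sentence_when(spans, reference, date_dialect)
    if (!is.null(when_k) && when_k$status == "resolved")
      last_when <- when_k
    eff_when <- when_k
    if (is.null(eff_when)) {
      eff_when <- if (!is.null(last_when)) {
        w <- last_when; w$provenance <- "inherited"; w
      } else {
        new_when(raw = note$authored_at, date = reference,
                 status = "resolved", provenance = "note-date-default")
      }
    }
    for (d in drafts) {
      d$when <- eff_when
      instances[[length(instances) + 1L]] <- d
    }
  }
  symptoms <- extract_symptoms(sym_all)
  pghd_extraction(note$note_id, instances, symptoms)
}

#' Extract a whole corpus
#'
#' Applies [extract_note()] to each note independently; shuffling note
#' order never changes any per-note result.
#'
#' @inheritParams extract_note
#' @param notes List of `pghd_note`.
#' @return List of `pghd_extraction`, aligned with `notes`.
#' @export
extract_corpus <- function(notes, lexicons, backend = "fallback",
                           date_dialect = "mdy", stop_terms = NULL) {
  lapply(notes, extract_note, lexicons = lexicons, backend = backend,
         date_dialect = date_dialect, stop_terms = stop_terms)
}
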
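# Ontology-subset lexicons and dictionary-based entity recognition.
#
# Medications link to RxNorm-style concept ids, symptoms to SNOMED CT-style
# ids, plus a unit-of-measure lexicon and a relative-temporal-trigger
# lexicon. File format is the contract: 3 tab-separated columns
# term<TAB>canonical<TAB>concept_id, `#` comment lines allowed, no header.
# Loaders accept user-supplied full ontology exports in the same shape.

VOCABULARIES <- c("medication", "symptom", "unit", "temporal_trigger")

#' Normalize a term for dictionary matching
#'
#' Lowercases, collapses internal whitespace to single spaces, and strips
#' leading/trailing punctuation. Idempotent: `normalize_term(normalize_term(x))`
#' equals `normalize_term(x)`.
#'
#' @param raw Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(raw) {
  x <- tolower(raw)
  x <- trimws(gsub("\\s+", " ", x))
  # strip alternating punctuation/whitespace from the edges to a fixed point
  repeat {
    y <- trimws(gsub("^[[:punct:]]+|[[:punct:]]+$", "", x))
    if (identical(y, x)) break
    x <- y
  }
  x
}

#' Load a lexicon from a 3-column TSV
#'
#' Columns are `term`, `canonical`, `concept_id` (tab-separated, UTF-8, no
#' header; leading `#` lines are comments). Terms are normalized with
#' [normalize_term()]; duplicate normalized terms keep the first occurrence
#' with a warning.
#'
#' @param path TSV path.
#' @param vocabulary One of `"medication"`, `"symptom"`, `"unit"`,
#'   `"temporal_trigger"`.
#' @return An object of class `pghd_lexicon` with fields `vocabulary`,
#'   `terms` (data frame `term`, `canonical`, `concept_id`) and
#'   `max_term_tokens` (token length of the longest entry).
#' @export
load_lexicon <- function(path, vocabulary) {
  vocabulary <- match.arg(vocabulary, VOCABULARIES)
  if (!file.exists(path)) stop("no such lexicon file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L)
    stop("empty lexicon file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 3L))
    stop("lexicon ", path, ": expected 3 tab-separated columns ",
         "(term, canonical, concept_id); line ", which(ncols < 3L)[1],
         " has ", ncols[ncols < 3L][1], call. = FALSE)
  df <- data.frame(term = normalize_term(vapply(parts, `[[`, "", 1L)),
                   canonical = vapply(parts, `[[`, "", 2L),
                   concept_id = vapply(parts, `[[`, "", 3L),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df$term)
  if (any(dup)) {
    warning(sprintf("lexicon %s: %d duplicate term(s) dropped (first kept): %s",
                    basename(path), sum(dup),
                    paste(unique(df$term[dup]), collapse = ", ")),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  structure(list(vocabulary = vocabulary, terms = df,
                 max_term_tokens = max(lengths(strsplit(df$term, " ",
                                                        fixed = TRUE)))),
            class = "pghd_lexicon")
}

#' @export
print.pghd_lexicon <- function(x, ...) {
  cat(sprintf("<pghd_lexicon %s> %d terms, longest %d token(s)\n",
              x$vocabulary, nrow(x$terms), x$max_term_tokens))
  invisible(x)
}

lexicon_lookup <- function(lexicon, normalized) {
  idx <- match(normalized, lexicon$terms$term)
  if (is.na(idx)) NULL else lexicon$terms[idx, , drop = FALSE]
}

#' Load the lexicons shipped with the package
#'
#' Illustrative ontology subsets (about 100 medications with brand/generic
#' pairs, 80 symptoms including mood terms, a unit-of-measure table and
#' relative-date triggers). Concept ids follow the RxNorm (`RX:`) and
#' SNOMED CT (`SCT:`) id style but are fixture values, not authoritative
#' ontology exports; point `dir` at your own 3-column TSVs to use full
#' RxNorm/SNOMED CT subsets.
#'
#' @param dir Directory containing `medications.tsv`, `symptoms.tsv`,
#'   `units.tsv`, `temporal_triggers.tsv`. Defaults to the package fixtures.
#' @return Named list of `pghd_lexicon`: `medication`, `symptom`, `unit`,
#'   `temporal_trigger`.
#' @export
default_lexicons <- function(dir = system.file("extdata", package = "pghdex")) {
  list(medication = load_lexicon(file.path(dir, "medications.tsv"), "medication"),
       symptom = load_lexicon(file.path(dir, "symptoms.tsv"), "symptom"),
       unit = load_lexicon(file.path(dir, "units.tsv"), "unit"),
       temporal_trigger = load_lexicon(file.path(dir, "temporal_triggers.tsv"),
                                       "temporal_trigger"))
}

#' Recognize entity mentions by longest dictionary match
#'
#' Greedy longest-match, left to right, over token n-grams up to the longest
#' lexicon entry; matched spans are consumed, so mentions from one lexicon
#' never overlap, and a term that is a prefix of a longer occurring term is
#' suppressed at that position ("water" inside "water irrigation solution").
#' Matching is case-insensitive via [normalize_term()].
#'
#' @param sentences Parsed sentences from [analyze_text()].
#' @param text The note text the sentences were parsed from.
#' @param lexicon A `pghd_lexicon`.
#' @param blocked Optional list, one integer vector of 0-based token indices
#'   per sentence, that matching must skip (used to give the medication
#'   vocabulary precedence over symptoms for ambiguous terms).
#' @param stop_terms Optional character vector of normalized terms to never
#'   match (e.g. a patient-name stop list).
#' @return Data frame of mentions: `start`, `end`, `surface`, `vocabulary`,
#'   `concept_id`, `canonical`, `sentence_index` (0-based),
#'   `head_token_index` (0-based index of the match's last token, head-final
#'   convention).
#' @export
match_entities <- function(sentences, text, lexicon, blocked = NULL,
                           stop_terms = NULL) {
  rows <- list()
  for (k in seq_along(sentences)) {
    tokens <- sentences[[k]]$tokens
    n <- nrow(tokens)
    if (n == 0L) next
    skip <- rep(FALSE, n)
    if (!is.null(blocked) && length(blocked) >= k && length(blocked[[k]]))
      skip[blocked[[k]] + 1L] <- TRUE
    i <- 1L
    while (i <= n) {
      if (skip[i] || tokens$pos[i] == "PUNCT") { i <- i + 1L; next }
      matched <- FALSE
      for (len in seq(min(lexicon$max_term_tokens, n - i + 1L), 1L)) {
        j <- i + len - 1L
        if (any(skip[i:j]) || any(tokens$pos[i:j] == "PUNCT")) next
        key <- normalize_term(paste(tokens$surface[i:j], collapse = " "))
        if (!is.null(stop_terms) && key %in% stop_terms) next
        hit <- lexicon_lookup(lexicon, key)
        if (!is.null(hit)) {
          start <- tokens$start[i]; end <- tokens$end[j]
          rows[[length(rows) + 1L]] <- data.frame(
            start = start, end = end,
            surface = slice_text(text, start, end),
            vocabulary = lexicon$vocabulary,
            concept_id = hit$concept_id, canonical = hit$canonical,
            sentence_index = k - 1L, head_token_index = tokens$index[j],
            stringsAsFactors = FALSE)
          i <- j + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), vocabulary = character(),
                      concept_id = character(), canonical = character(),
                      sentence_index = integer(),
                      head_token_index = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
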
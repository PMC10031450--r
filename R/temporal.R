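# Temporal expression detection and normalization.
#
# Detects clock times (6:00, 6:00 am), absolute dates (November 5, 11/5/2020
# per dialect) and relative triggers ("yesterday", "2 days ago", "a few days
# ago"), and resolves relative expressions against the note's authorship
# date. Resolution is a pure function of (span text, reference date): there
# is no wall-clock dependence anywhere. Non-numeric phrasal referents ("a
# few days ago") are flagged unresolved rather than guessed.

MONTHS <- c("january", "february", "march", "april", "may", "june", "july",
            "august", "september", "october", "november", "december")
MONTH_ABBR <- substr(MONTHS, 1, 3)

new_when <- function(raw, date = NULL, time_of_day = NULL,
                     status = c("resolved", "unresolved_phrasal"),
                     provenance = NULL, ambiguous_meridiem = FALSE) {
  status <- match.arg(status)
  if (status == "resolved" && is.null(date) && is.null(time_of_day))
    stop("resolved 'when' needs a date or a time of day", call. = FALSE)
  if (status == "unresolved_phrasal" && (!is.null(date) || !is.null(time_of_day)))
    stop("unresolved_phrasal 'when' keeps only the raw text", call. = FALSE)
  w <- list(raw = raw, date = date, time_of_day = time_of_day,
            status = status, provenance = provenance)
  if (isTRUE(ambiguous_meridiem)) w$ambiguous_meridiem <- TRUE
  structure(w, class = "pghd_when")
}

month_number <- function(word) {
  w <- tolower(word)
  m <- match(w, MONTHS)
  if (is.na(m)) m <- match(substr(w, 1, 3), MONTH_ABBR)
  m
}

#' Detect temporal expressions in a parsed sentence
#'
#' Finds (a) clock times `h:mm` with optional `am`/`pm`, (b) absolute dates
#' as month name + day with optional year, or numeric `m/d[/y]` dates read
#' per `date_dialect`, (c) relative triggers from the temporal-trigger
#' lexicon plus the open patterns "N days ago" / "N weeks ago".
#'
#' @param sentence One parsed sentence from [analyze_text()].
#' @param trigger_lexicon The `temporal_trigger` lexicon; its `canonical`
#'   column is the trigger kind (`offset_days` or `phrasal`) and
#'   `concept_id` the signed day offset for `offset_days` rows.
#' @param text Note text.
#' @param date_dialect `"mdy"` (default) or `"dmy"` for numeric dates.
#' @return Data frame of spans: `start`, `end`, `surface`, `kind`
#'   (`clock`, `absolute`, `relative`, `phrasal`), `value` (day offset for
#'   relative spans, `NA` otherwise).
#' @export
detect_temporal <- function(sentence, trigger_lexicon, text,
                            date_dialect = c("mdy", "dmy")) {
  date_dialect <- match.arg(date_dialect)
  tokens <- sentence$tokens
  n <- nrow(tokens)
  spans <- list()
  used <- rep(FALSE, n)
  add <- function(i, j, kind, value = NA_real_) {
    start <- tokens$start[i]; end <- tokens$end[j]
    spans[[length(spans) + 1L]] <<- data.frame(
      start = start, end = end, surface = slice_text(text, start, end),
      kind = kind, value = value, stringsAsFactors = FALSE)
    used[i:j] <<- TRUE
  }
  lower <- tolower(tokens$surface)

  # Clock times, absorbing a following am/pm token.
  for (i in seq_len(n)) {
    if (used[i] || !grepl(CLOCK_RE, tokens$surface[i])) next
    j <- if (i < n && lower[i + 1L] %in% c("am", "pm")) i + 1L else i
    add(i, j, "clock")
  }
  # Month-name dates: <Month> <day>[ ,] [year]
  for (i in seq_len(n)) {
    if (used[i] || is.na(month_number(lower[i]))) next
    if (i < n && grepl("^[0-9]{1,2}$", tokens$surface[i + 1L])) {
      j <- i + 1L
      k <- j + 1L
      if (k <= n && tokens$surface[k] == ",") k <- k + 1L
      if (k <= n && grepl("^[0-9]{4}$", tokens$surface[k])) j <- k
      add(i, j, "absolute")
    }
  }
  # Numeric dates (single token, tokenizer keeps m/d/y together).
  for (i in seq_len(n)) {
    if (!used[i] && grepl(DATE_RE, tokens$surface[i])) add(i, i, "absolute")
  }
  # Open relative patterns: N days ago / N weeks ago.
  for (i in seq_len(n)) {
    if (used[i] || !grepl("^[0-9]+$", tokens$surface[i])) next
    if (i + 2L <= n && lower[i + 1L] %in% c("day", "days", "week", "weeks") &&
        lower[i + 2L] == "ago") {
      mult <- if (startsWith(lower[i + 1L], "week")) 7 else 1
      add(i, i + 2L, "relative",
          value = -mult * as.numeric(tokens$surface[i]))
    }
  }
  # Lexicon triggers, longest first.
  max_len <- trigger_lexicon$max_term_tokens
  i <- 1L
  while (i <= n) {
    if (used[i]) { i <- i + 1L; next }
    hit_here <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      j <- i + len - 1L
      if (any(used[i:j])) next
      key <- normalize_term(paste(tokens$surface[i:j], collapse = " "))
      hit <- lexicon_lookup(trigger_lexicon, key)
      if (!is.null(hit)) {
        if (hit$canonical == "phrasal") add(i, j, "phrasal")
        else add(i, j, "relative", value = as.numeric(hit$concept_id))
        i <- j + 1L; hit_here <- TRUE; break
      }
    }
    if (!hit_here) i <- i + 1L
  }
  if (length(spans) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), kind = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, spans)
  out[order(out$start), , drop = FALSE]
}

parse_clock <- function(surface) {
  m <- regmatches(surface,
                  regexec("([0-9]{1,2}):([0-9]{2})\\s*(am|pm)?",
                          tolower(surface)))[[1]]
  h <- as.integer(m[2]); mi <- as.integer(m[3]); mer <- m[4]
  if (is.na(h) || h > 23 || mi > 59) return(NULL)
  ambiguous <- !nzchar(mer)
  if (mer == "pm" && h < 12) h <- h + 12L
  if (mer == "am" && h == 12) h <- 0L
  list(time = sprintf("%02d:%02d", h, mi), ambiguous = ambiguous)
}

#' Resolve a temporal span against a reference date
#'
#' "yesterday" resolves to the reference minus one day, "today" to the
#' reference, "N days ago" to reference − N; clock times normalize am/pm to
#' 24-hour `HH:MM` (meridiem-less times resolve with an ambiguity flag);
#' absolute dates default the year to the reference year. Phrasal
#' quantifiers without a number ("a few days ago") come back with status
#' `unresolved_phrasal` — a status, not an error.
#'
#' @param span One row of [detect_temporal()] output (data frame or list).
#' @param reference A `Date`: the note's authorship date.
#' @param date_dialect `"mdy"` or `"dmy"` for numeric dates.
#' @return A `pghd_when` with fields `raw`, `date`, `time_of_day`, `status`.
#' @export
resolve_when <- function(span, reference, date_dialect = c("mdy", "dmy")) {
  date_dialect <- match.arg(date_dialect)
  stopifnot(inherits(reference, "Date"))
  kind <- span$kind; raw <- span$surface
  if (kind == "phrasal")
    return(new_when(raw, status = "unresolved_phrasal"))
  if (kind == "clock") {
    ck <- parse_clock(raw)
    if (is.null(ck)) return(new_when(raw, status = "unresolved_phrasal"))
    return(new_when(raw, time_of_day = ck$time, status = "resolved",
                    ambiguous_meridiem = ck$ambiguous))
  }
  if (kind == "relative")
    return(new_when(raw, date = reference + span$value, status = "resolved"))
  # absolute
  toks <- tokenize_span(raw)$surface
  mn <- month_number(toks[1])
  if (!is.na(mn)) {
    day <- as.integer(toks[2])
    year <- if (length(toks) >= 3L && grepl("^[0-9]{4}$", toks[length(toks)]))
      as.integer(toks[length(toks)]) else as.integer(format(reference, "%Y"))
    d <- as.Date(sprintf("%04d-%02d-%02d", year, mn, day))
    if (is.na(d)) return(new_when(raw, status = "unresolved_phrasal"))
    return(new_when(raw, date = d, status = "resolved"))
  }
  parts <- as.integer(strsplit(raw, "/", fixed = TRUE)[[1]])
  if (date_dialect == "mdy") { m <- parts[1]; dd <- parts[2] }
  else { dd <- parts[1]; m <- parts[2] }
  year <- if (length(parts) == 3L) {
    y <- parts[3]; if (y < 100L) y + 2000L else y
  } else as.integer(format(reference, "%Y"))
  d <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", year, m, dd)),
                error = function(e) as.Date(NA))
  if (is.na(d)) return(new_when(raw, status = "unresolved_phrasal"))
  new_when(raw, date = d, status = "resolved")
}

# Sentence-level temporal policy: merge the sentence's resolved spans into
# one `when` (first resolved date + first clock time); a sentence without
# any temporal expression inherits the nearest preceding resolved `when` in
# the note, else falls back to the authorship date with provenance
# "note-date-default".
sentence_when <- function(spans, reference, date_dialect = "mdy") {
  if (nrow(spans) == 0L) return(NULL)
  resolved <- lapply(seq_len(nrow(spans)), function(r)
    resolve_when(spans[r, , drop = FALSE], reference, date_dialect))
  dates <- Filter(function(w) w$status == "resolved" && !is.null(w$date),
                  resolved)
  times <- Filter(function(w) w$status == "resolved" &&
                    !is.null(w$time_of_day), resolved)
  if (length(dates) == 0L && length(times) == 0L) {
    phr <- Filter(function(w) w$status == "unresolved_phrasal", resolved)
    if (length(phr)) {
      w <- phr[[1]]; w$provenance <- "sentence"; return(w)
    }
    return(NULL)
  }
  raws <- unique(vapply(c(dates[seq_len(min(1, length(dates)))],
                          times[seq_len(min(1, length(times)))]),
                        function(w) w$raw, character(1)))
  new_when(raw = paste(raws, collapse = "; "),
           date = if (length(dates)) dates[[1]]$date else NULL,
           time_of_day = if (length(times)) times[[1]]$time_of_day else NULL,
           status = "resolved", provenance = "sentence",
           ambiguous_meridiem = length(times) > 0 &&
             isTRUE(times[[1]]$ambiguous_meridiem))
}
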
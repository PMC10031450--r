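# Linguistic backend: sentence splitting, tokenization, coarse POS tagging
# and dependency arcs. The "fallback" backend is a deterministic rule system
# (no model download, byte-identical output across runs); a "pretrained"
# backend slot exists for wiring in an external biomedical model suite.

POS_TAGS <- c("NOUN", "PROPN", "VERB", "NUM", "ADP", "DET", "ADJ", "ADV",
              "PUNCT", "OTHER")

# Token pattern, most specific first: numeric dates, clock times, numeric
# ranges, decimals and integers stay single tokens so dose and time atoms
# survive tokenization.
TOKEN_RE <- paste0(
  "[0-9]{1,2}/[0-9]{1,2}(?:/[0-9]{2,4})?",     # numeric date 11/5/2020
  "|[0-9]{1,2}:[0-9]{2}",                      # clock time 6:00
  "|[0-9]+(?:\\.[0-9]+)?-[0-9]+(?:\\.[0-9]+)?",# range 1-2
  "|[0-9]+\\.[0-9]+",                          # decimal 2.6
  "|[0-9]+",                                   # integer
  "|[A-Za-z]+(?:'[A-Za-z]+)*",                 # word, keeps apostrophes
  "|\\.\\.\\.|…",                         # ellipsis
  "|[^\\sA-Za-z0-9]"                           # any other symbol
)

ADP_WORDS <- c("at", "of", "in", "on", "for", "with", "to", "over", "by",
               "after", "before", "around", "during", "from", "per",
               "through", "until")
DET_WORDS <- c("a", "an", "the", "his", "her", "their", "my", "our", "its",
               "this", "that", "these", "those", "another", "some", "any",
               "no", "every")
VERB_WORDS <- c("gave", "give", "given", "gives", "giving", "take", "takes",
                "took", "taking", "taken", "start", "started", "starting",
                "starts", "stop", "stopped", "stopping", "switch",
                "switched", "continue", "continued", "will", "is", "are",
                "was", "were", "be", "been", "being", "has", "have", "had",
                "do", "does", "did", "doing", "done", "went", "go", "goes",
                "get", "gets", "got", "seems", "seem", "feel", "feels",
                "felt", "report", "reported", "recorded", "used", "use",
                "hanging", "gone", "says", "said")

CLOCK_RE <- "^[0-9]{1,2}:[0-9]{2}$"
DATE_RE <- "^[0-9]{1,2}/[0-9]{1,2}(/[0-9]{2,4})?$"
NUMERIC_RE <- "^[0-9]+(\\.[0-9]+)?(-[0-9]+(\\.[0-9]+)?)?$"

tokenize_span <- function(text, offset = 0L) {
  m <- gregexpr(TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  starts <- as.integer(m) - 1L + offset
  lens <- attr(m, "match.length")
  data.frame(surface = regmatches(text, gregexpr(TOKEN_RE, text,
                                                 perl = TRUE))[[1]],
             start = starts, end = starts + lens,
             stringsAsFactors = FALSE)
}

#' Split text into sentence spans
#'
#' Boundaries are `.`, `!`, `?` followed by whitespace or end of text, and
#' ellipses (`...` or the single-character ellipsis) anywhere. Decimal
#' points inside numbers are never boundaries (no whitespace follows them).
#'
#' @param text Note text.
#' @return Data frame with 0-based half-open columns `start`, `end`, one row
#'   per non-empty sentence.
#' @export
split_sentences <- function(text) {
  m <- gregexpr("(\\.\\.\\.|…)|[.!?](?=\\s|$)", text, perl = TRUE)[[1]]
  bounds <- if (m[1] == -1L) integer() else
    as.integer(m) - 1L + attr(m, "match.length")  # 0-based end of boundary
  cuts <- sort(unique(c(bounds, nchar(text))))
  out <- list(); prev <- 0L
  for (cut in cuts) {
    seg <- slice_text(text, prev, cut)
    lead_ws <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail_ws <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s <- prev + lead_ws; e <- cut - trail_ws
    if (e > s && nzchar(trimws(seg)))
      out[[length(out) + 1L]] <- c(start = s, end = e)
    prev <- cut
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, out))
}

# Single-token lexicon membership sets used for POS hinting.
lexicon_pos_hints <- function(lexicons) {
  one_token_terms <- function(lex) {
    if (is.null(lex)) return(character())
    terms <- lex$terms$term
    terms[!grepl(" ", terms, fixed = TRUE)]
  }
  list(unit = one_token_terms(lexicons$unit),
       med = one_token_terms(lexicons$medication),
       sym = one_token_terms(lexicons$symptom))
}

assign_pos <- function(tokens, hints, sent_start) {
  surf <- tokens$surface
  lower <- tolower(surf)
  pos <- rep("NOUN", length(surf))
  pos[grepl(NUMERIC_RE, surf) | grepl(CLOCK_RE, surf) |
      grepl(DATE_RE, surf)] <- "NUM"
  is_word <- grepl("^[A-Za-z]", surf)
  pos[!is_word & pos != "NUM"] <- "PUNCT"
  pos[is_word & lower %in% ADP_WORDS] <- "ADP"
  pos[is_word & lower %in% DET_WORDS] <- "DET"
  pos[is_word & lower %in% VERB_WORDS] <- "VERB"
  hinted <- is_word & !(lower %in% c(ADP_WORDS, DET_WORDS, VERB_WORDS))
  pos[hinted & lower %in% hints$unit] <- "NOUN"
  pos[hinted & lower %in% hints$med] <- "PROPN"
  pos[hinted & lower %in% hints$sym] <- "NOUN"
  # Capitalized tokens past the first are treated as proper nouns (names).
  capped <- hinted & grepl("^[A-Z]", surf) & tokens$start > sent_start
  pos[capped & !(lower %in% c(hints$unit, hints$sym))] <- "PROPN"
  pos
}

assign_deps <- function(tokens) {
  n <- nrow(tokens)
  pos <- tokens$pos
  head <- integer(n); dep <- character(n)
  root <- which(pos == "VERB")[1]
  if (is.na(root)) root <- which(pos %in% c("NOUN", "PROPN"))[1]
  if (is.na(root)) root <- 1L
  for (i in seq_len(n)) {
    if (i == root) {
      head[i] <- i; dep[i] <- "root"
    } else if (pos[i] == "NUM" && i < n && pos[i + 1L] %in% c("NOUN", "PROPN")) {
      head[i] <- i + 1L; dep[i] <- "nummod"
    } else if (pos[i] == "ADP") {
      prior <- which(pos[seq_len(i - 1L)] %in% c("VERB", "NOUN", "PROPN"))
      head[i] <- if (length(prior)) max(prior) else root
      dep[i] <- "prep"
    } else if (pos[i] == "PUNCT") {
      head[i] <- root; dep[i] <- "punct"
    } else if (pos[i] == "DET") {
      head[i] <- root; dep[i] <- "det"
    } else {
      head[i] <- root; dep[i] <- "dep"
    }
  }
  # Guard against self-loops outside the root (cannot occur by construction,
  # but the tree invariant is load-bearing downstream).
  bad <- which(head == seq_len(n) & seq_len(n) != root)
  head[bad] <- root
  tokens$head <- head - 1L   # 0-based like token indices
  tokens$dep <- dep
  tokens
}

#' Parse note text into sentences, tokens, POS tags and dependency arcs
#'
#' The fallback backend is fully deterministic: whitespace/punctuation
#' tokenization that preserves decimals, ranges, clock times and numeric
#' dates as single tokens; coarse POS from closed word lists, numeric shape
#' and lexicon membership (unit terms are NOUN, medication terms PROPN);
#' dependency arcs from three rules (a NUM immediately before a noun is its
#' `nummod`, a preposition attaches to the nearest preceding verb or noun,
#' everything else attaches to the sentence root, the first verb).
#'
#' @param text Note text (non-empty).
#' @param lexicons Named list of lexicons as returned by
#'   [default_lexicons()]; used only for POS hints.
#' @param backend `"fallback"` (rule-based, always available) or
#'   `"pretrained"` (external model suite; errors if not wired in).
#' @return List of parsed sentences; each is a list with `sent_start`,
#'   `sent_end` (0-based half-open offsets) and `tokens`, a data frame with
#'   columns `index` (0-based), `surface`, `start`, `end`, `pos`, `head`
#'   (0-based index of the governing token, self for the root), `dep`.
#' @export
analyze_text <- function(text, lexicons, backend = c("fallback", "pretrained")) {
  backend <- match.arg(backend)
  if (backend == "pretrained")
    stop("backend 'pretrained' is not available: no external model suite ",
         "is configured; use backend = 'fallback'", call. = FALSE)
  if (!nzchar(trimws(text))) return(list())
  sents <- split_sentences(text)
  hints <- lexicon_pos_hints(lexicons)
  out <- vector("list", nrow(sents))
  for (k in seq_len(nrow(sents))) {
    seg <- slice_text(text, sents$start[k], sents$end[k])
    tokens <- tokenize_span(seg, offset = sents$start[k])
    if (nrow(tokens) == 0L) {
      out[[k]] <- list(sent_start = sents$start[k], sent_end = sents$end[k],
                       tokens = tokens)
      next
    }
    tokens$pos <- assign_pos(tokens, hints, sents$start[k])
    tokens <- assign_deps(tokens)
    tokens$index <- seq_len(nrow(tokens)) - 1L
    out[[k]] <- list(sent_start = sents$start[k], sent_end = sents$end[k],
                     tokens = tokens[, c("index", "surface", "start", "end",
                                         "pos", "head", "dep")])
  }
  out[!vapply(out, function(s) nrow(s$tokens) == 0L, logical(1))]
}

# Undirected dependency-path distance between two token indices (0-based)
# within one sentence; used for quantity-to-medication attachment.
dep_path_distance <- function(tokens, i, j) {
  if (i == j) return(0L)
  n <- nrow(tokens)
  adj <- vector("list", n)
  for (t in seq_len(n)) {
    h <- tokens$head[t] + 1L
    if (h != t) {
      adj[[t]] <- c(adj[[t]], h)
      adj[[h]] <- c(adj[[h]], t)
    }
  }
  src <- i + 1L; dst <- j + 1L
  dist <- rep(NA_integer_, n); dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        if (nb == dst) return(dist[nb])
        queue <- c(queue, nb)
      }
    }
  }
  dist[dst]
}
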
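# Synthetic PGHD generator: diary-style caregiver notes with known gold
# annotations. Emulates short (1-3 sentence) notes mixing medication events
# (name + dose + unit + time), symptom observations and empty diary
# entries, with a configurable fraction of notes passed through a
# transcription-noise channel. Gold is emitted at generation time, never
# re-derived from the (possibly corrupted) text, so noise creates genuine
# prediction-vs-gold divergence.

GEN_NAMES <- c("Alex", "Sam", "Jordan", "Riley", "Casey", "Morgan",
               "Jamie", "Quinn")
# A real first name that is also a medication brand in the fixture lexicon;
# sampled at `ambiguous_name_rate` to reproduce the name/medication
# false-positive error mode.
AMBIGUOUS_NAME <- "Allegra"

GEN_MEDS <- c("Benadryl", "gabapentin", "Tylenol", "Keppra", "Zyrtec",
              "Claritin", "Miralax", "albuterol", "melatonin", "baclofen",
              "prednisone", "amoxicillin", "Singulair", "Zofran", "Ativan",
              "Trileptal", "clonidine", "omeprazole")
GEN_SYMPTOMS <- c("runny nose", "fever", "cough", "congestion", "vomiting",
                  "diarrhea", "rash", "headache", "seizure", "tremor",
                  "sore throat", "wheezing", "fatigue", "dizziness",
                  "irritability", "anxiety", "drooling", "reflux",
                  "constipation", "swelling")
GEN_TIMES <- list(c("6:00 am", "06:00"), c("8:30 am", "08:30"),
                  c("12:00 pm", "12:00"), c("4:15 pm", "16:15"),
                  c("9:00 pm", "21:00"), c("7:45 am", "07:45"))
GEN_QTYS <- c("1", "2", "3", "4", "5", "0.5", "1.5", "2.5", "7.5", "10")
GEN_RATES <- c("3.2", "2.6", "2", "1.6", "1.2", "0.6")
NUMBER_WORDS <- c("1" = "one", "2" = "two", "3" = "three", "4" = "four",
                  "5" = "five", "6" = "six", "7" = "seven", "8" = "eight",
                  "9" = "nine", "10" = "ten")

#' Configuration for the synthetic note generator
#'
#' Defaults mirror the corpus the generator emulates: the four-way category
#' mix 17/33/13/24 over 87 notes (medication-only, symptom-only, both,
#' none) and an 18% rate of notes carrying at least one transcription
#' error.
#'
#' @param n_notes Number of notes (>= 1).
#' @param category_mix Probabilities over `medication_only`, `symptom_only`,
#'   `both`, `none`; must sum to 1.
#' @param asr_error_note_rate Fraction of notes receiving 1-3 text
#'   corruptions (gold is never altered).
#' @param seed Integer seed; (config, seed) fully determines the corpus.
#' @param ambiguous_name_rate Probability that a note's patient name is the
#'   name/medication homograph `"Allegra"` instead of a neutral first name;
#'   0 keeps generated text free of dictionary false positives.
#' @return Object of class `pghd_gen_config`.
#' @export
generator_config <- function(n_notes = 87,
                             category_mix = c(medication_only = 17 / 87,
                                              symptom_only = 33 / 87,
                                              both = 13 / 87,
                                              none = 24 / 87),
                             asr_error_note_rate = 0.18,
                             seed = 1L,
                             ambiguous_name_rate = 0) {
  if (n_notes < 1L) stop("n_notes must be >= 1", call. = FALSE)
  if (length(category_mix) != 4L ||
      !setequal(names(category_mix), CATEGORIES))
    stop("category_mix needs the four categories ",
         paste(CATEGORIES, collapse = ", "), call. = FALSE)
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1", call. = FALSE)
  if (any(category_mix < 0)) stop("category_mix must be non-negative",
                                  call. = FALSE)
  if (asr_error_note_rate < 0 || asr_error_note_rate > 1)
    stop("asr_error_note_rate must be in [0, 1]", call. = FALSE)
  if (ambiguous_name_rate < 0 || ambiguous_name_rate > 1)
    stop("ambiguous_name_rate must be in [0, 1]", call. = FALSE)
  structure(list(n_notes = as.integer(n_notes),
                 category_mix = category_mix[CATEGORIES],
                 asr_error_note_rate = asr_error_note_rate,
                 seed = as.integer(seed),
                 ambiguous_name_rate = ambiguous_name_rate),
            class = "pghd_gen_config")
}

# One medication-bearing sentence plus its gold instances. `authored` is
# the note's authorship date; gold `when` follows the documented attachment
# policy (explicit expression if the sentence has one, else the note date).
gen_med_sentence <- function(name, authored) {
  med <- sample(GEN_MEDS, 1)
  kind <- sample(c("dose_time", "rate", "taper", "bare", "days_ago"), 1,
                 prob = c(0.3, 0.2, 0.2, 0.15, 0.15))
  canon_of <- function(term) term  # canonical filled by caller via lexicon
  if (kind == "dose_time") {
    qty <- sample(GEN_QTYS, 1)
    tm <- GEN_TIMES[[sample(length(GEN_TIMES), 1)]]
    list(text = sprintf("Gave %s %s %s at %s.", name, qty, med, tm[1]),
         instances = list(list(medication = med,
                               quantity = as.numeric(qty),
                               when = list(time_of_day = tm[2]))))
  } else if (kind == "rate") {
    qty <- sample(GEN_RATES, 1)
    yesterday <- stats::runif(1) < 0.5
    txt <- if (yesterday)
      sprintf("Yesterday we started %s at a rate of %s ml.", med, qty)
    else sprintf("Started %s at a rate of %s ml.", med, qty)
    when <- list(date = if (yesterday) authored - 1 else authored)
    list(text = txt,
         instances = list(list(medication = med, quantity = as.numeric(qty),
                               unit = "milliliter", when = when)))
  } else if (kind == "taper") {
    k <- sample(2:4, 1)
    rates <- GEN_RATES[sort(sample(length(GEN_RATES), k))]
    txt <- sprintf(
      "Yesterday we started %s at a rate of %s ml, then we will switch to %s ml%s.",
      med, rates[1], rates[2],
      if (k > 2) paste0(", then ",
                        paste(sprintf("%s ml", rates[3:k]), collapse = ", then "))
      else "")
    when <- list(date = authored - 1)
    list(text = txt,
         instances = lapply(rates, function(q)
           list(medication = med, quantity = as.numeric(q),
                unit = "milliliter", when = when)))
  } else if (kind == "days_ago") {
    nd <- sample(2:6, 1)
    list(text = sprintf("Started %s %d days ago.", med, nd),
         instances = list(list(medication = med,
                               when = list(date = authored - nd))))
  } else {
    list(text = sprintf("%s took %s this morning.", name, med),
         instances = list(list(medication = med,
                               when = list(date = authored))))
  }
}

gen_symptom_sentence <- function(name) {
  k <- sample(1:2, 1)
  syms <- sample(GEN_SYMPTOMS, k)
  if (k == 1L) {
    txt <- sample(c(sprintf("%s has %s.", name, syms[1]),
                    sprintf("Has some %s.", syms[1]),
                    sprintf("Overall doing fine but still %s.", syms[1])), 1)
  } else {
    txt <- sample(c(sprintf("Has %s and %s today.", syms[1], syms[2]),
                    sprintf("%s has %s but no %s.", name, syms[1], syms[2])),
                  1)
  }
  list(text = txt, symptoms = syms)
}

gen_filler_sentence <- function() {
  sample(c("Overall doing okay today.", "Quiet day at home.",
           "Went to school and enjoyed the afternoon.",
           "Slept through the whole evening.",
           "Nothing new to report."), 1)
}

#' Generate a synthetic note corpus with gold annotations
#'
#' Deterministic given the seed: the caller's RNG state is saved and
#' restored. Gold canonical names are looked up in the supplied lexicons so
#' that annotation and extraction share one concept inventory.
#'
#' @param config A `pghd_gen_config` from [generator_config()].
#' @param lexicons Lexicon list from [default_lexicons()].
#' @return List with `notes` (list of `pghd_note`), `gold` (list of
#'   `pghd_gold`) and `noisy` (logical vector: which notes were corrupted).
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicons = default_lexicons()) {
  stopifnot(inherits(config, "pghd_gen_config"))
  med_canon <- function(term) {
    hit <- lexicon_lookup(lexicons$medication, normalize_term(term))
    if (is.null(hit)) stop("generator medication not in lexicon: ", term,
                           call. = FALSE)
    hit$canonical
  }
  sym_canon <- function(term) {
    hit <- lexicon_lookup(lexicons$symptom, normalize_term(term))
    if (is.null(hit)) stop("generator symptom not in lexicon: ", term,
                           call. = FALSE)
    hit$canonical
  }
  confusions <- default_asr_confusions()
  with_seed(config$seed, {
    cats <- sample(CATEGORIES, config$n_notes, replace = TRUE,
                   prob = config$category_mix)
    noisy <- stats::runif(config$n_notes) < config$asr_error_note_rate
    notes <- vector("list", config$n_notes)
    gold <- vector("list", config$n_notes)
    for (i in seq_len(config$n_notes)) {
      authored <- as.Date("2020-11-01") + sample(0:13, 1)
      authored_at <- sprintf("%sT%02d:%02d:00", format(authored),
                             sample(6:21, 1), sample(0:59, 1))
      name <- if (stats::runif(1) < config$ambiguous_name_rate)
        AMBIGUOUS_NAME else sample(GEN_NAMES, 1)
      sentences <- character()
      gold_instances <- list()
      gold_symptoms <- character()
      cat_i <- cats[i]
      if (cat_i %in% c("medication_only", "both")) {
        ms <- gen_med_sentence(name, authored)
        sentences <- c(sentences, ms$text)
        gold_instances <- lapply(ms$instances, function(gi) {
          gi$medication <- med_canon(gi$medication)
          gi
        })
      }
      if (cat_i %in% c("symptom_only", "both")) {
        n_sym_sent <- if (cat_i == "symptom_only") sample(1:2, 1) else 1L
        for (s in seq_len(n_sym_sent)) {
          ss <- gen_symptom_sentence(name)
          sentences <- c(sentences, ss$text)
          gold_symptoms <- c(gold_symptoms,
                             vapply(ss$symptoms, sym_canon, character(1)))
        }
      }
      if (cat_i == "none" || (length(sentences) < 3L && stats::runif(1) < 0.25))
        sentences <- c(sentences, gen_filler_sentence())
      if (cat_i == "none" && stats::runif(1) < 0.4)
        sentences <- c(sentences, gen_filler_sentence())
      text <- paste(sentences, collapse = " ")
      notes[[i]] <- pghd_note(
        note_id = sprintf("note-%04d", i), text = text,
        authored_at = authored_at,
        modality = if (stats::runif(1) < 78 / 87) "voice_transcript"
                   else "typed",
        author_id = sprintf("author-%02d", sample(24, 1)))
      gold[[i]] <- pghd_gold(sprintf("note-%04d", i), gold_instances,
                             gold_symptoms)
    }
    # Noise is a second pass so the content stream (and hence the gold) is
    # identical across asr_error_note_rate settings at a fixed seed.
    for (i in which(noisy))
      notes[[i]]$text <- apply_asr_noise(notes[[i]]$text, 1, confusions)
    list(notes = notes, gold = gold, noisy = noisy)
  })
}

#' Homophone confusion table used by the noise channel
#'
#' @param path TSV with columns `from`, `to`; defaults to the shipped table.
#' @return Data frame with columns `from`, `to`.
#' @export
default_asr_confusions <- function(path = system.file("extdata",
                                                      "asr_confusions.tsv",
                                                      package = "pghdex")) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#",
                          col.names = c("from", "to"),
                          colClasses = "character")
  df
}

#' Apply transcription-style noise to note text
#'
#' Draws 1-3 corruptions, each applied with probability `intensity`, from:
#' near-phonetic whole-word substitution via the confusion table
#' ("ml" to "mil", "Benadryl" to "bena drill"), a digit-to-word swap
#' ("2" to "two"), casing loss, and punctuation drop. Uses R's RNG (seed
#' it, or call from [generate_corpus()] which seeds it for you).
#'
#' @param text Input text.
#' @param intensity Corruption probability in `[0, 1]`; 0 returns the text
#'   unchanged.
#' @param confusions Confusion table from [default_asr_confusions()].
#' @return Corrupted text.
#' @export
apply_asr_noise <- function(text, intensity = 1,
                            confusions = default_asr_confusions()) {
  stopifnot(intensity >= 0, intensity <= 1)
  if (intensity == 0) return(text)
  n_corr <- sample(1:3, 1)
  for (k in seq_len(n_corr)) {
    if (stats::runif(1) > intensity) next
    types <- sample(c("homophone", "numberword", "casing", "punct"),
                    4, prob = c(0.5, 0.25, 0.15, 0.1))
    for (ty in types) {
      if (ty == "homophone") {
        present <- which(vapply(confusions$from, function(f)
          grepl(paste0("(?i)\\b", f, "\\b"), text, perl = TRUE),
          logical(1)))
        if (!length(present)) next
        r <- present[sample(length(present), 1)]
        text <- sub(paste0("(?i)\\b", confusions$from[r], "\\b"),
                    confusions$to[r], text, perl = TRUE)
        break
      } else if (ty == "numberword") {
        digit_re <- function(d)
          paste0("(?<![0-9.:/-])\\b", d, "\\b(?![.:/-])")
        present <- names(NUMBER_WORDS)[vapply(names(NUMBER_WORDS),
          function(d) grepl(digit_re(d), text, perl = TRUE), logical(1))]
        if (!length(present)) next
        d <- present[sample(length(present), 1)]
        text <- sub(digit_re(d), NUMBER_WORDS[[d]], text, perl = TRUE)
        break
      } else if (ty == "casing") {
        if (text == tolower(text)) next
        text <- tolower(text)
        break
      } else {
        if (grepl(",", text, fixed = TRUE)) {
          text <- sub(",", "", text, fixed = TRUE)
          break
        } else if (grepl("\\.$", text)) {
          text <- sub("\\.$", "", text)
          break
        }
        next
      }
    }
  }
  text
}
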
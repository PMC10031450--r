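# Instance-level evaluation: subcomponent matching, the all-subcomponents
# instance-correctness rule, and micro-averaged precision/recall/F1 per
# data component (medication_instance, medication, unit, quantity, date,
# symptom).

COMPONENTS <- c("medication_instance", "medication", "unit", "quantity",
                "date", "symptom")

empty_counts <- function() {
  data.frame(component = COMPONENTS, tp = 0L, fp = 0L, fn = 0L,
             stringsAsFactors = FALSE)
}

bump <- function(counts, component, what, by = 1L) {
  i <- match(component, counts$component)
  counts[i, what] <- counts[i, what] + by
  counts
}

# Normalized-string equality for canonical names.
canon_eq <- function(a, b) normalize_term(a) == normalize_term(b)

num_eq <- function(a, b) is.finite(a) && is.finite(b) && abs(a - b) < 1e-9

pred_when_parts <- function(w) {
  if (is.null(w) || w$status != "resolved") return(NULL)
  list(date = w$date, time_of_day = w$time_of_day)
}

when_eq <- function(gold_w, pred_w) {
  # Joint date/time equality: every part present on either side must agree.
  same_part <- function(a, b, eq) {
    if (is.null(a) && is.null(b)) return(TRUE)
    if (is.null(a) || is.null(b)) return(FALSE)
    eq(a, b)
  }
  same_part(gold_w$date, pred_w$date, function(a, b) a == b) &&
    same_part(gold_w$time_of_day, pred_w$time_of_day,
              function(a, b) a == b)
}

#' Is a predicted instance fully correct against its matched gold instance?
#'
#' True iff every subcomponent present in gold (quantity, unit, date/time)
#' is present and equal in the prediction, and the prediction presents no
#' subcomponent absent from gold. The medication names are assumed matched.
#'
#' @param pred A `med_instance`.
#' @param gold A gold instance (list with `medication` and optional
#'   `quantity`, `unit`, `when`).
#' @return Logical.
#' @export
instance_correct <- function(pred, gold) {
  pw <- pred_when_parts(pred$when)
  if (!is.null(gold$quantity)) {
    if (is.null(pred$quantity) || !num_eq(pred$quantity, gold$quantity))
      return(FALSE)
  } else if (!is.null(pred$quantity)) return(FALSE)
  if (!is.null(gold$unit)) {
    if (is.null(pred$unit) || !canon_eq(pred$unit$canonical, gold$unit))
      return(FALSE)
  } else if (!is.null(pred$unit)) return(FALSE)
  if (!is.null(gold$when)) {
    if (is.null(pw) || !when_eq(gold$when, pw)) return(FALSE)
  } else if (!is.null(pw)) return(FALSE)
  TRUE
}

# Agreement score used to pick among same-medication candidates during
# matching: number of agreeing subcomponents.
pair_score <- function(pred, gold) {
  s <- 0L
  if (!is.null(gold$quantity) && !is.null(pred$quantity) &&
      num_eq(pred$quantity, gold$quantity)) s <- s + 1L
  if (!is.null(gold$unit) && !is.null(pred$unit) &&
      canon_eq(pred$unit$canonical, gold$unit)) s <- s + 1L
  pw <- pred_when_parts(pred$when)
  if (!is.null(gold$when) && !is.null(pw) && when_eq(gold$when, pw))
    s <- s + 1L
  s
}

count_subcomponents <- function(counts, pred, gold) {
  # Within a matched pair: per subcomponent, equal -> tp; gold-only -> fn;
  # pred-only -> fp; both present but unequal -> fn and fp.
  score_part <- function(counts, comp, gp, pp, eq) {
    if (!is.null(gp) && !is.null(pp)) {
      if (eq(gp, pp)) bump(counts, comp, "tp")
      else bump(bump(counts, comp, "fn"), comp, "fp")
    } else if (!is.null(gp)) bump(counts, comp, "fn")
    else if (!is.null(pp)) bump(counts, comp, "fp")
    else counts
  }
  pw <- pred_when_parts(pred$when)
  counts <- score_part(counts, "quantity", gold$quantity, pred$quantity,
                       num_eq)
  counts <- score_part(counts, "unit", gold$unit,
                       if (is.null(pred$unit)) NULL else pred$unit$canonical,
                       canon_eq)
  counts <- score_part(counts, "date", gold$when, pw, when_eq)
  counts
}

count_unmatched_pred <- function(counts, pred) {
  counts <- bump(counts, "medication", "fp")
  counts <- bump(counts, "medication_instance", "fp")
  if (!is.null(pred$quantity)) counts <- bump(counts, "quantity", "fp")
  if (!is.null(pred$unit)) counts <- bump(counts, "unit", "fp")
  if (!is.null(pred_when_parts(pred$when)))
    counts <- bump(counts, "date", "fp")
  counts
}

count_unmatched_gold <- function(counts, gold) {
  counts <- bump(counts, "medication", "fn")
  counts <- bump(counts, "medication_instance", "fn")
  if (!is.null(gold$quantity)) counts <- bump(counts, "quantity", "fn")
  if (!is.null(gold$unit)) counts <- bump(counts, "unit", "fn")
  if (!is.null(gold$when)) counts <- bump(counts, "date", "fn")
  counts
}

#' Score one note's prediction against its gold annotation
#'
#' Predicted and gold instances are matched by canonical medication name
#' (normalized-string equality); among same-name candidates, pairs with the
#' most agreeing subcomponents are matched first (greedy). Within a matched
#' pair each subcomponent present in gold scores tp if equal, else fn (plus
#' fp if the prediction offers a conflicting value); predicted
#' subcomponents absent from gold score fp. Unmatched predicted instances
#' are fp for every presented subcomponent, unmatched gold fn likewise.
#' Symptoms are scored as a multiset intersection on canonical names.
#'
#' @param pred A `pghd_extraction`.
#' @param gold The `pghd_gold` for the same `note_id`.
#' @return Data frame of confusion counts (`component`, `tp`, `fp`, `fn`).
#' @export
match_note <- function(pred, gold) {
  if (!identical(pred$note_id, gold$note_id))
    stop("note_id mismatch: ", pred$note_id, " vs ", gold$note_id,
         call. = FALSE)
  counts <- empty_counts()
  preds <- pred$medication_instances
  golds <- gold$gold_instances
  np <- length(preds); ng <- length(golds)
  pred_used <- rep(FALSE, np); gold_used <- rep(FALSE, ng)
  if (np > 0L && ng > 0L) {
    cand <- list()
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      if (canon_eq(preds[[i]]$medication$canonical, golds[[j]]$medication))
        cand[[length(cand) + 1L]] <-
          c(i = i, j = j, s = pair_score(preds[[i]], golds[[j]]))
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(-cand[, "s"], cand[, "i"], cand[, "j"]), ,
                   drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, "i"]; j <- cand[r, "j"]
        if (pred_used[i] || gold_used[j]) next
        pred_used[i] <- TRUE; gold_used[j] <- TRUE
        counts <- bump(counts, "medication", "tp")
        counts <- count_subcomponents(counts, preds[[i]], golds[[j]])
        if (instance_correct(preds[[i]], golds[[j]]))
          counts <- bump(counts, "medication_instance", "tp")
        else
          counts <- bump(bump(counts, "medication_instance", "fp"),
                         "medication_instance", "fn")
      }
    }
  }
  for (i in which(!pred_used)) counts <- count_unmatched_pred(counts, preds[[i]])
  for (j in which(!gold_used)) counts <- count_unmatched_gold(counts, golds[[j]])

  ps <- normalize_term(vapply(pred$symptom_mentions,
                              function(s) s$symptom$canonical, character(1)))
  gs <- normalize_term(gold$gold_symptoms)
  tp <- 0L
  gs_pool <- gs
  for (s in ps) {
    hit <- match(s, gs_pool)
    if (!is.na(hit)) { tp <- tp + 1L; gs_pool <- gs_pool[-hit] }
  }
  counts <- bump(counts, "symptom", "tp", tp)
  counts <- bump(counts, "symptom", "fp", length(ps) - tp)
  counts <- bump(counts, "symptom", "fn", length(gs) - tp)
  counts
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`; any 0/0
#' denominator yields 0 by convention (logged once per call).
#'
#' @param tp,fp,fn Non-negative counts; `tp` may also be a data frame or
#'   list with fields `tp`, `fp`, `fn`.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
prf <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  p <- if (tp + fp == 0) { degenerate <- TRUE; 0 } else tp / (tp + fp)
  r <- if (tp + fn == 0) { degenerate <- TRUE; 0 } else tp / (tp + fn)
  f <- if (p + r == 0) { degenerate <- TRUE; 0 } else 2 * p * r / (p + r)
  if (degenerate)
    pghd_log("DEBUG", sprintf("0/0 convention applied (tp=%s fp=%s fn=%s)",
                              tp, fp, fn))
  c(precision = p, recall = r, f1 = f)
}

#' Evaluate a corpus of predictions against gold annotations
#'
#' Sums per-note confusion counts per component and applies [prf()]
#' (micro-averaging). `notes_n` counts the notes whose gold contains at
#' least one item of the component; `instances_n` counts gold items of the
#' component. A gold note without a prediction is scored against an empty
#' prediction with a warning; a prediction without gold is scored against
#' an empty gold annotation.
#'
#' @param preds List of `pghd_extraction`.
#' @param golds List of `pghd_gold`.
#' @return Object of class `pghd_metrics`: list with `counts` (summed
#'   confusion counts) and `report` (data frame `component`, `precision`,
#'   `recall`, `f1`, `notes_n`, `instances_n`; scores rounded to 2 d.p.).
#' @export
evaluate_corpus <- function(preds, golds) {
  pid <- vapply(preds, function(p) p$note_id, character(1))
  gid <- vapply(golds, function(g) g$note_id, character(1))
  if (anyDuplicated(gid)) stop("duplicate note_id in gold", call. = FALSE)
  counts <- empty_counts()
  notes_n <- stats::setNames(rep(0L, length(COMPONENTS)), COMPONENTS)
  instances_n <- notes_n
  for (k in seq_along(golds)) {
    g <- golds[[k]]
    i <- match(g$note_id, pid)
    p <- if (is.na(i)) {
      warning("gold note without prediction, scored as empty: ", g$note_id,
              call. = FALSE)
      pghd_extraction(g$note_id)
    } else preds[[i]]
    nc <- match_note(p, g)
    counts$tp <- counts$tp + nc$tp
    counts$fp <- counts$fp + nc$fp
    counts$fn <- counts$fn + nc$fn
    has <- gold_component_presence(g)
    notes_n <- notes_n + as.integer(has$any)
    instances_n <- instances_n + has$count
  }
  for (i in which(!(pid %in% gid))) {
    nc <- match_note(preds[[i]], pghd_gold(preds[[i]]$note_id))
    counts$tp <- counts$tp + nc$tp
    counts$fp <- counts$fp + nc$fp
    counts$fn <- counts$fn + nc$fn
  }
  scores <- t(vapply(seq_len(nrow(counts)), function(r)
    prf(counts$tp[r], counts$fp[r], counts$fn[r]), numeric(3)))
  report <- data.frame(component = counts$component,
                       precision = round(scores[, 1], 2),
                       recall = round(scores[, 2], 2),
                       f1 = round(scores[, 3], 2),
                       notes_n = as.integer(notes_n[counts$component]),
                       instances_n = as.integer(instances_n[counts$component]),
                       stringsAsFactors = FALSE)
  structure(list(counts = counts, report = report), class = "pghd_metrics")
}

gold_component_presence <- function(g) {
  n_inst <- length(g$gold_instances)
  n_qty <- sum(vapply(g$gold_instances,
                      function(x) !is.null(x$quantity), logical(1)))
  n_unit <- sum(vapply(g$gold_instances,
                       function(x) !is.null(x$unit), logical(1)))
  n_when <- sum(vapply(g$gold_instances,
                       function(x) !is.null(x$when), logical(1)))
  n_sym <- length(g$gold_symptoms)
  count <- c(medication_instance = n_inst, medication = n_inst,
             unit = n_unit, quantity = n_qty, date = n_when,
             symptom = n_sym)
  list(count = count[COMPONENTS], any = count[COMPONENTS] > 0L)
}

#' @export
print.pghd_metrics <- function(x, ...) {
  cat("Per-component evaluation (micro-averaged):\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Columns exactly: `component`, `precision`, `recall`, `f1`, `notes_n`,
#' `instances_n`.
#'
#' @param metrics A `pghd_metrics` from [evaluate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(metrics, path) {
  utils::write.table(metrics$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
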
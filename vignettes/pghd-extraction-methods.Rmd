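---
title: "Extracting medication and symptom information from patient notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting medication and symptom information from patient notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pghdex)
```

## The problem and the approach

Free-text patient-generated health data (PGHD) — short diary notes written
or dictated by patients and caregivers — carries clinically useful facts in
an unstructured form: medication events (name, quantity, unit, date/time)
and symptom observations. `pghdex` extracts both with a zero-shot,
dictionary-plus-rules design: no task-specific training data, every
decision inspectable. The pipeline is

sentence parse → entity recognition against ontology subsets → dependency
rules for dose assembly → temporal normalization → categorization,

with an instance-level evaluation scheme and a synthetic corpus generator
closing the loop. This vignette explains each stage's model, its tunable
parameters, and the design decisions that were genuinely open.

## Linguistic backend

Extraction rules only consume *coarse* structure: a 10-tag POS inventory
(`NOUN, PROPN, VERB, NUM, ADP, DET, ADJ, ADV, PUNCT, OTHER`) and untyped
head arcs plus the `nummod`/`prep` relations. The backend contract is
therefore small, and two implementations can satisfy it:

* **fallback** (default, always available): deterministic rules. The
  tokenizer keeps dose and time atoms whole — decimals (`2.6`), ranges
  (`1-2`), clock times (`6:00`), numeric dates (`11/5/2020`) are single
  tokens; sentence boundaries are terminal punctuation before whitespace,
  plus ellipses, so a decimal point never splits a sentence. POS comes
  from numeric shape, closed word lists (prepositions, determiners, a verb
  list covering diary usage), and lexicon membership (unit terms are
  `NOUN`, medication terms `PROPN`). Dependency arcs come from three
  rules: a `NUM` immediately before a noun is its `nummod`; a preposition
  attaches to the nearest preceding verb/noun; everything else attaches to
  the sentence root (the first verb). Every output tree is single-rooted
  and acyclic by construction — a property the test suite fuzzes because
  the attachment search downstream does a BFS over those arcs.
* **pretrained**: a slot for an external biomedical model suite mapped
  into the same coarse contract. Selecting it without a wired model is a
  hard error naming the backend; all shipped tests and results use the
  fallback, which keeps the whole suite hermetic and bit-reproducible.

The extraction rules key on coarse structure rather than any specific
parser's label inventory precisely so that backends can differ in their
fine-grained labels without changing extraction behavior.

## Lexicons and entity recognition

Entity recognition is exact dictionary matching (after normalization:
lowercase, single-spaced, edge punctuation stripped to a fixed point —
normalization is idempotent) with greedy longest match left-to-right, up
to the longest entry in the lexicon. Longest match resolves the classic
containment ambiguity: with both *water* and *water irrigation solution*
in the medication table, only the three-token term fires at that position.
Matched spans are consumed, so per-vocabulary mentions never overlap; when
a term is in both the medication and symptom tables, medication wins (a
deterministic tie-break, logged in the mention's vocabulary field).

The shipped tables are illustrative subsets in the RxNorm / SNOMED CT id
*style* (~108 medication rows with brand+generic pairs, ~81 symptom rows,
29 unit rows); the 3-column TSV format is the contract, and full ontology
exports in the same shape drop in via `default_lexicons(dir = ...)`.
Two deliberate inclusions mirror known properties of this data: mood terms
(*happiness*, *sadness*) are in the symptom table, since mood bears on
health state; and the medication table retains common-word and
name-overlapping entries (*water*; *Allegra*, also a first name), which
reproduces the documented false-positive mode of dictionary linking. A
`stop_terms` hook on matching lets a deployment suppress known patient
names; it is off by default so the error mode stays measurable. Fuzzy
matching is deliberately absent: it would blur the zero-shot baseline
this package is meant to pin down.

## Dose assembly

Quantity–unit pairing uses two rules within a sentence, in priority
order, with each `NUM` token used at most once:

* **Q1**: `NUM --nummod--> unit-lexicon token` ⇒ (quantity, unit) —
  "a rate of **2.6 ml**";
* **Q2**: `NUM` headed by (or immediately preceding) a medication mention
  ⇒ (quantity, no unit) — "**2** Benadryl".

Clock-time and date-shaped tokens are excluded: `6:00` is temporal, never
a dose, which is exactly the collision the antihistamine example would
otherwise produce. Ranges take their first number (`1-2` → 1); quantities
must be positive. Each pair then attaches to the medication mention whose
head token is closest along the undirected dependency path, with ties
broken by character distance and then leftmost mention. Instance
granularity: one instance per (medication, pair); several pairs on one
medication enumerate in text order — this is what turns a taper sentence
into four instances with descending rates — and a medication with no pair
is still one (bare) instance. Rules never cross sentence boundaries;
information split across sentences is a known, accepted failure mode of
diary text rather than something the rules guess at.

## Temporal normalization

Detection covers clock times (with optional meridiem), month-name and
numeric dates, lexicon triggers ("yesterday", "last week"), and the open
patterns "N days/weeks ago". Resolution is a pure function of (span text,
reference date) — the reference is always the note's authorship date, and
nothing reads the wall clock. Choices worth stating:

* Meridiem-less times ("at 6:00") resolve to `06:00` but carry an
  `ambiguous_meridiem` flag: information is preserved without guessing.
* Non-numeric phrasal referents ("a few days ago") become status
  `unresolved_phrasal` with the raw text kept — a status, not an error.
* Numeric-date dialect is an explicit switch (`mdy` default, `dmy`
  available), never inferred from content.
* Attachment: a sentence's temporal expressions attach to *all* of its
  medication instances (first date + first clock time merged); a sentence
  without one inherits the nearest preceding resolved expression, else
  the authorship date with provenance `note-date-default`. This mirrors
  diary semantics — an undated medication line in a dated note happened on
  the note's date — and the provenance field keeps the inference auditable.

## Evaluation

Gold annotations are name-anchored, not span-anchored: reference
judgments are made against the sentence, so matching is by canonical
medication name at note scope. Among same-name candidates, pairs with the
most agreeing subcomponents match first (greedy). Within a matched pair,
each subcomponent present in gold scores tp if equal (quantity:
numeric equality; unit/medication: canonical equality; when: joint
date-and/or-time equality), else fn — plus fp when the prediction offers a
conflicting value; predicted subcomponents absent from gold are fp.
Unmatched instances contribute fp (predicted) or fn (gold) for every
presented subcomponent. The instance row applies the all-or-nothing rule:
a matched pair is a tp only if `instance_correct()` holds — every gold
subcomponent right and nothing spurious; otherwise it is both an fp and an
fn. Symptoms score as per-note multisets of canonicals: repeated mentions
are not deduplicated, each occurrence counts on both sides.

Scores are micro-averaged (counts summed over the corpus, then
`P`, `R`, `F1`), with the 0/0 → 0 convention for degenerate cells, logged
so it is never silent. Reports round to 2 decimals; the harmonic-mean
identity `F1 = 2PR/(P+R)` at that precision is itself checked in the test
suite for the component rows where published-style rounding is
self-consistent. Mood terms extracted as symptoms score as tp whenever
the gold includes them.

## The synthetic corpus: what it emulates, and what it does not

The generator stands in for a private caregiver-note corpus. Its defaults
are the study conditions it emulates: 87 notes, category mix
17/33/13/24 (medication-only / symptom-only / both / none), 18% of notes
carrying at least one transcription error, voice-to-typed ratio 78:9, and
1–3 sentence notes built from dose (*"Gave {name} {qty} {med} at
{time}."*), rate, taper (2–4 descending rates), bare-medication,
days-ago, symptom and filler templates. Authorship dates span a two-week
window, matching the diary-study design. Gold is frozen at generation
time; the noise channel (homophone table, digit-to-word swaps guarded so
decimals and clock times stay intact, casing loss, punctuation drop) runs
as a second pass, so the content stream — and therefore the gold — is
identical across noise rates at a fixed seed. All randomness flows
through one seed with the caller's RNG state restored.

Two generator semantics follow from the pipeline's stated scope, and are
worth making explicit. Symptom gold is *mention-level*: "has a cough but
no fever" contributes both cough and fever, because polarity is out of
scope and the reference protocol judges extractions as asserted mentions.
Medication gold always carries a `when` — the explicit expression if the
template states one, else the authorship date — matching the documented
note-date-default attachment. Under these semantics a noise-free corpus
is extracted perfectly (the end-to-end oracle test: P = R = F1 = 1.0 at
200 notes), which is exactly what makes the generator a usable oracle:
any future rule regression surfaces as a broken identity. The
`ambiguous_name_rate` parameter (default 0) injects the name/medication
homograph to reproduce the dictionary false-positive mode on demand;
it is a test probe, not part of the emulated conditions.

What passing these tests does **not** show: real dictated notes have
richer phrasing than the templates, out-of-lexicon medications and
misspellings the exact matcher will miss, cross-sentence dose splits, and
negation that a mention-level system scores wrong by design. Synthetic
perfection is an internal-consistency statement, not a claim about
real-world recall.

## Numerical and degenerate-input choices

* Offsets are 0-based, half-open, over code points, everywhere.
* Quantities are decimals; equality in scoring is exact up to 1e-9.
* Empty or whitespace-only text parses to no sentences and an empty
  result of category `none`; content never raises.
* Malformed JSONL lines skip with a line-numbered warning; a file with
  zero valid notes is a hard error.
* Duplicate lexicon terms keep the first row with a warning; empty or
  under-columned lexicon files are hard errors.
* Problem sizes in the shipped tests (200-note parse/oracle corpora,
  40-note × 10-seed × 3-rate noise sweep, counts to 20 for the metric
  enumeration) were chosen as the smallest sizes at which the properties
  are meaningfully exercised.

## Known limitations

No negation or uncertainty handling; no dosage frequency or route
(*b.i.d.*, *PO*); no durations or recurring schedules; no fuzzy or
embedding-based linking; no cross-note aggregation into timelines; exact
matching bounds recall by lexicon coverage. These are scope boundaries,
not oversights: each is either explicitly out of the design's scope or an
extension point (`stop_terms`, user lexicon directories, the `pretrained`
backend slot).
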
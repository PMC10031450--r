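Package: pghdex
Title: Medication and Symptom Extraction from Patient-Generated Health Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A zero-shot, rule-based natural language processing pipeline for
    free-text patient-generated health data (PGHD). Recognizes medication and
    symptom mentions by dictionary lookup against RxNorm-style and SNOMED
    CT-style concept tables, assembles medication instances (name, quantity,
    unit, date/time) by traversing part-of-speech tags and dependency parse
    trees, and normalizes relative temporal expressions against the note's
    authorship date. Ships an instance-level evaluation scheme (precision,
    recall, F1 per data component) and a seeded synthetic note generator with
    gold annotations and a configurable transcription-noise channel, so the
    whole pipeline is testable without access to private clinical notes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
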
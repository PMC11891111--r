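Package: cuilink
Title: Neuro-Symbolic Medical Entity Linking for Spanish Oncology Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes medical entities in Spanish oncology clinical notes and
    normalizes them to Concept Unique Identifiers (CUIs) in a UMLS-style
    controlled vocabulary. Candidate terms are retrieved from an in-process
    BM25 index built over a background knowledge base (labels, synonyms,
    semantic types, definitions, per-label linking scores), filtered by
    Ratcliff-Obershelp string similarity against a threshold, and resolved by
    a heuristic decision rule; ambiguous mentions are disambiguated by a
    pluggable large-language-model client via chain-of-thought prompting,
    with a translate-to-English-and-retry fallback. Includes Accuracy and
    Accuracy@N evaluation, configuration sweeps, a deterministic synthetic
    vocabulary/notes/benchmark generator, and mock LLM clients so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
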
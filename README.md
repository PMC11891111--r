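# cuilink

Medical entity linking for Spanish oncology clinical notes.

Clinical notes name the same concept in many ways — "ca. de mama", "cáncer
de mama", "mama parte derecha" — while interoperable records need Concept
Unique Identifiers (CUIs) from a controlled vocabulary such as UMLS.
`cuilink` implements a neuro-symbolic linking pipeline for this problem,
aimed at clinical-NLP practitioners who need reproducible, auditable
normalization of Spanish mentions:

1. **NER** — notes are preprocessed (acronym expansion, e.g. "ca." →
   "cáncer"; sentence splitting) and mentions are recognized with a context
   label (`Cancer concept`, `Cancer location`, `Surgery`, ...). A
   deterministic gazetteer recognizer ships for testing; trained models
   plug in behind the same interface.
2. **Entity linking (MEL)** — a background knowledge base is built from the
   vocabulary: every (CUI, label) pair becomes a BM25-indexed document with
   label, synonym and definition fields, plus a per-label *linking score*
   (the number of source vocabularies asserting that label). Five query
   types of increasing fuzziness retrieve the top-*k* candidates
   (`Exact`, `Basic_Fuzzy`, `Multi_match_SPA`, `Multi_match`,
   `Multi_match_boosted`).
3. **Filtering & decision** — candidates are scored against the mention
   with the Ratcliff–Obershelp ratio `s(a,b) = 2M / (|a|+|b|)` and compared
   with a threshold θ_sim (default 0.96). Exactly one confident CUI → a
   direct link, no LLM. No candidate → translation fallback. Anything
   else → disambiguation.
4. **Disambiguation (MED)** — a chain-of-thought prompt lists each
   candidate's CUI, label, semantic group and preferred definition
   (NCI-first) and asks a pluggable LLM client to pick the CUI(s) or to
   declare the candidates inadequate and translate the term to English,
   after which the search is repeated (bounded retry).

Evaluation uses set-based Accuracy = |G ∩ R| / |G| and Accuracy@N over
the ranked output, the natural metrics when one mention can carry several
valid CUIs (e.g. "chemotherapy" ↔ {C0013216, C3665472, C1571591}).
A deterministic synthetic generator (vocabulary with homonyms, synonyms,
duplicate labels across sources, notes, gold benchmark, mock LLM clients)
makes every stage testable offline.

## Worked example

```r
library(cuilink)

# a five-record toy vocabulary: one Spanish/English concept, one
# Spanish-only concept, and the homonym "boost" under two CUIs
records <- load_simple_vocab("vocab.jsonl")
index   <- build_index(aggregate_concepts(records))
index
#> <vocab_index> 5 documents over 4 concepts (hash c607ad80)
#>   BM25 k1=1.2 b=0.75 delta=1

cfg    <- pipeline_config(q_type = "Exact", theta_sim = 0.96)
truth  <- data.frame(surface = "boost", context = "Treatment name",
                     cui = "C0183683")
client <- mock_llm("oracle", truth = truth)

# a unique confident match links directly -- the LLM is never consulted
link_entity(list(surface = "carcinoma", label = "Cancer concept"),
            index, cfg, client)
#> <linked_entity> 'carcinoma' [Cancer concept] -> C0007097 (LINKED_DIRECT)

# "boost" matches two CUIs at full similarity: the decision is AMBIGUOUS
# and the chain-of-thought disambiguator resolves it from the context
link_entity(list(surface = "boost", label = "Treatment name"),
            index, cfg, client)
#> <linked_entity> 'boost' [Treatment name] -> C0183683 (LINKED_LLM)

similarity("mama derecha", "mama parte derecha")
#> [1] 0.8
accuracy(c("C0013216", "C3665472", "C1571591"), "C0013216")
#> [1] 0.3333333
```

The `0.8` is the Ratcliff–Obershelp ratio (12 matched characters over
lengths 12 + 18): below θ_sim = 0.96, so such a candidate would go to the
disambiguator rather than link directly. The `0.33` reads "one of the
three valid CUIs was returned".

Vocabularies can also be read from UMLS Rich Release Format files with
`parse_rrf("MRCONSO.RRF", "MRSTY.RRF", "MRDEF.RRF")` (a UMLS licence is
required for the real files; none is needed anywhere in this package).

A thin command-line front end with `synth`, `build-bk`, `link` and `eval`
subcommands is installed at
`system.file("cli", "cuilink.R", package = "cuilink")`.

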
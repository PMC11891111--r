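---
title: "Linking Spanish oncology mentions to CUIs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking Spanish oncology mentions to CUIs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuilink)
```

# The problem

Spanish oncology notes mention concepts in free variation — abbreviations
("ca."), inflected or re-ordered phrases ("mama parte derecha" for the
vocabulary label "mama derecha"), and homonyms ("boost" as a radiotherapy
dose or a nutritional supplement). Normalization means mapping each
recognized mention, together with its context label, to the Concept
Unique Identifier(s) of a UMLS-style vocabulary. `cuilink` treats this as
a retrieve–filter–decide–disambiguate pipeline that mimics how a human
coder works: search the term as written; inspect near matches; if nothing
fits, translate to English (most vocabulary content is English-only) and
search again.

# The background knowledge base

`aggregate_concepts()` groups vocabulary records per CUI. Within a
concept, labels are grouped by a normalized form (NFC, lowercase, accent
folding, whitespace collapse — chosen so Spanish and English variants
such as "cáncer"/"cancer" compare equal; raw labels are preserved for
display). The **linking score** of a normalized label is the number of
source records asserting it: a label three organizations agree on ranks
above a label only one uses. Two invariants are enforced and tested:
per concept, linking scores over distinct normalized labels sum to the
number of input records; and aggregation of shuffled input is identical
(all reductions are order-free, ties broken by normalized label, then
language, then CUI).

Homonymy is never collapsed: the same surface under two CUIs stays in
both entries, which is precisely the case the disambiguator exists for.

## Retrieval model

Every (CUI, label) pair is one document with three fields: its own label,
the concept's other labels (synonyms), and the concept's definitions.
Scoring is Okapi BM25 with a lower-bound term (BM25+ style):

$$ w(t,d) = \log\!\Big(1+\tfrac{N-df_t+0.5}{df_t+0.5}\Big)\;
   \Big(\frac{(k_1+1)\,tf_{t,d}}{k_1(1-b+b\,dl_d/avgdl)+tf_{t,d}}
   + \delta\Big) $$

with defaults $k_1 = 1.2$, $b = 0.75$, $\delta = 1$, all configurable.
The lower-bound variant was chosen because it is standard, closed-form
and therefore checkable against a brute-force oracle; document
frequencies and average lengths are kept per field. Five query types
span the precision/recall range a practitioner actually sweeps:

* **Exact** — normalized-label equality only.
* **Basic_Fuzzy** — every query token must match a label token within a
  Levenshtein budget of 1 edit (tokens of length ≤ 5) or 2 edits
  (longer), the usual search-engine "auto" convention; AND semantics.
* **Multi_match_SPA / Multi_match** — highest fuzziness: OR semantics,
  per-token fuzzy matching across all three fields, best-field scoring
  with the definition field down-weighted ×0.5 (definitions are context,
  not names); the SPA variant restricts to Spanish-language labels.
* **Multi_match_boosted** — as Multi_match, with candidates whose label
  contains a boost word (default cancer lexicon: cáncer, cancer,
  carcinoma, tumor, neoplasia, maligno) multiplied by a boost factor
  (default 2).

Giving the Multi_match family the same per-token edit budget as
Basic_Fuzzy is a deliberate design choice: it makes the hit sets
provably nested (Exact ⊆ Basic_Fuzzy ⊆ Multi_match, and
Multi_match_SPA ⊆ Multi_match), a property the test suite checks on
hundreds of random mention/index pairs. Results are ordered by
(retrieval score, linking score, CUI, label) — BM25 primary, linking
score as the tie-break; both values are exposed on every candidate so a
user can re-rank. On indexes of ≤ 100 documents the entire ranking is
verified against an exhaustive scorer implementing the formulas above.

# Filtering and the decision rule

Each candidate is compared with the mention by the Ratcliff–Obershelp
ratio $s(a,b) = 2M/(|a|+|b|)$, where $M$ is the total length of matching
blocks found by recursively taking the longest common substring
(computed on normalized strings; ties broken by earliest position).
For the motivating pair:

```{r}
similarity("mama derecha", "mama parte derecha")
```

Candidates with $s \ge \theta_{sim}$ (default 0.96, the value at which
the accuracy sweep of the original case study peaks) form the
*confident* set, grouped by CUI keeping the best label per concept. The
decision is three-way:

* no retrieved candidate at all → `NO_CANDIDATE`;
* confident set = exactly one CUI → `DIRECT_LINK`, no LLM call;
* otherwise → `AMBIGUOUS`: either ≥ 2 confident CUIs compete, or
  nothing reached the threshold and the full retrieved set is passed on
  *flagged low-confidence*.

The low-confidence pass-through is required so that the disambiguator is
consulted exactly when "all candidates are below the threshold" — with a
strict drop, such mentions could never be resolved. A consequence
accepted by design: an `AMBIGUOUS` payload can contain a single
(low-confidence) CUI; the prompt is well-formed for one candidate.

# Disambiguation

The prompt lists the mention, its context label and, per candidate, the
CUI, label, semantic group and one definition. When a concept has
several definitions the NCI one is preferred (an authoritative source
for cancer), then a fixed source-priority list, then the first
remaining; a placeholder marks concepts without definitions. Three
prompt styles ship (`CoT` default, `FewShot` with two synthetic
exemplars, `ZeroShot`); decoding defaults are temperature 0 and 512 max
tokens, chosen for determinism. The chain-of-thought style asks the
model to reason stepwise and finish with a machine-readable line —
`ANSWER: <CUIs>` or `ANSWER: NONE | TRANSLATION: <term>` — and the
parser falls back to pattern extraction on free text. Two hard
guarantees hold regardless of the model: selected CUIs are always a
subset of the offered ones (anything else is treated as inadequate),
and parsing is total (unparseable text becomes `INADEQUATE` without a
translation).

The client is one function, `complete(prompt) -> list(text)`. Shipped
implementations are the deterministic mocks (`oracle`, `adversarial`,
`scripted`); a hosted-API adapter is a few lines over `llm_client()` but
is not shipped, so the package itself never needs network access.

# The pipeline loop

Per entity: search Spanish-first; `DIRECT_LINK` short-circuits;
`AMBIGUOUS` goes to the LLM; `NO_CANDIDATE` or an inadequate candidate
set triggers translation to English and one more retrieval pass, up to
`max_translation_rounds` (default 1 — one Spanish plus one English pass;
the retry is re-entered with the same decision logic, so a translated
term that is again ambiguous is disambiguated again). An entity that
survives all rounds is `UNLINKED`, which is a result, not an error;
per-entity failures inside a note are isolated so batch runs continue.
Three audited invariants: every recognized entity yields exactly one
result; LLM disambiguation calls equal the number of `AMBIGUOUS`
decisions (zero on a corpus where every mention has a unique confident
match); and retrieval passes per entity never exceed
1 + `max_translation_rounds`.

Because a linked (mention, context) pair never needs re-deriving, an
optional cache keyed by (normalized surface, label, config/index hash)
replays results; changing the configuration or rebuilding the index
invalidates it. With mock clients and a fixed seed, repeated runs are
byte-identical.

# Evaluation

`accuracy(G, R) = |G ∩ R| / |G|` and `accuracy_at_n()` over the ranked
CUI list (final CUIs first, then remaining candidates in retrieval
order, deduplicated — so Accuracy@N is non-decreasing in N, which is
asserted). Gold records are matched by (normalized text, context);
duplicates in gold are rejected, and unmatched gold records score 0
rather than being skipped, so silent drops are penalized. Means are
unweighted. `sweep_configs()` re-runs the pipeline per configuration —
the harness used for query-type, threshold and prompt ablations.

# The synthetic generator

`gen_vocab()`/`gen_notes()` emulate the structural features the pipeline
must survive: duplicate labels across fake source vocabularies (linking
scores > 1), bilingual concepts with 2/3 of concepts carrying a Spanish
label (≈ 40/60 Spanish/English records, echoing the English dominance of
real metathesauri), homonym twins sharing a Spanish surface under
different contexts, English-only concepts reachable only via
translation, definitions with an NCI-tagged subset, planted mentions
with recorded offsets, optional one-character typos, and matched mock
clients. Synthetic CUIs use the reserved C9xxxxxx range so fixtures can
be mixed with real CUIs without collision. All randomness derives from
the `synth_spec()` seed.

Two deliberate constraints keep the emitted ground truth well-defined:
the Spanish and English surface inventories are disjoint after
normalization (a shared surface would make "English-only" and the
translation fallback ambiguous in ways the truth map cannot express),
and homonym twins carry different context labels, since context is
exactly the signal the disambiguator uses.

What passing on this data does *not* show: real clinical prose is far
noisier than the templated sentences; real UMLS is three orders of
magnitude larger, with richer semantic types and cross-lingual overlap
the generator deliberately excludes; and the oracle mock brackets the
best case of an LLM, as the adversarial mock brackets the worst. Results
on synthetic corpora certify the machinery (retrieval correctness,
decision totality, call accounting, determinism), not clinical accuracy.

# Numerical and degenerate-input choices

* Similarity of two empty strings is 1 (consistent with s(a,a) = 1);
  empty-vs-non-empty is 0.
* "Confident" means $s \ge \theta_{sim}$ (ties at the threshold are
  confident).
* Exact-query scores use the same BM25 weights as fuzzy queries so all
  rankings are on one scale.
* An empty concept table cannot be indexed (error); an empty candidate
  list is a valid `NO_CANDIDATE`.
* The index serializes to plain text (manifest + JSON-lines); loading
  rebuilds collection statistics and verifies the build hash, making
  round trips score-identical.
* Test and acceptance workloads use vocabularies of 30–80 concepts
  (≤ ~160 index documents), corpora of ~200+ mentions, 1000 similarity
  pairs and 25 queries per query type against the brute-force oracle —
  sizes at which exhaustive reference scoring is exact and fast.

# Known limitations

* The gazetteer maps each surface to one context label, so on the NER
  path a homonym surface gets a single label; benchmark-style evaluation
  of homonyms therefore enters at `link_entity()` with gold contexts,
  the same place a trained recognizer would hand over.
* Basic_Fuzzy applies the edit budget per token with AND semantics;
  token order is not scored.
* No hosted LLM adapter is bundled; `llm_client()` is the extension
  point.
* Translation uses one candidate translation per round; alternative
  translations are not explored.
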
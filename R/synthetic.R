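#' Specification for synthetic vocabulary/corpus generation
#'
#' Drives a fully deterministic generator that emulates the structure the
#' linker faces in production: a multilingual vocabulary with duplicate
#' labels across source vocabularies (exercising linking scores),
#' synonyms, homonyms (one surface, several CUIs — the case that needs
#' LLM disambiguation), per-CUI definitions from several sources with an
#' NCI subset, Spanish clinical-style notes with planted mentions, and a
#' gold benchmark. English labels dominate by default (60/40), mirroring
#' real metathesaurus language composition.
#'
#' @param seed RNG seed; fixes every random choice.
#' @param n_concepts number of base concepts (before homonym twins).
#' @param p_spanish fraction of concepts that also carry a Spanish label
#'   (2/3 gives a 40/60 Spanish/English record split).
#' @param synonym_rate probability that a concept's Spanish label is
#'   duplicated by a second source vocabulary (linking score 2).
#' @param homonym_rate fraction of concepts that get a homonym twin: a
#'   new CUI sharing the same Spanish surface under a different context.
#' @param typo_rate probability that a planted note mention carries a
#'   one-character typo.
#' @param oov_rate probability that a planted mention is the Spanish
#'   surface of an English-only concept (reachable only via translation).
#' @param label_set context labels assigned to concepts.
#' @param n_notes,mentions_per_note corpus size.
#' @return a `synth_spec` object.
#' @export
synth_spec <- function(seed = 7L, n_concepts = 50L, p_spanish = 2 / 3,
                       synonym_rate = 0.3, homonym_rate = 0.1,
                       typo_rate = 0, oov_rate = 0,
                       label_set = c("Cancer concept", "Cancer type",
                                     "Cancer subtype", "Cancer expansion",
                                     "Cancer location", "Surgery",
                                     "Treatment drug", "Treatment name"),
                       n_notes = 20L, mentions_per_note = 2L) {
  stopifnot(n_concepts >= 1L,
            all(c(p_spanish, synonym_rate, homonym_rate, typo_rate,
                  oov_rate) >= 0),
            all(c(p_spanish, synonym_rate, homonym_rate, typo_rate,
                  oov_rate) <= 1))
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 p_spanish = p_spanish, synonym_rate = synonym_rate,
                 homonym_rate = homonym_rate, typo_rate = typo_rate,
                 oov_rate = oov_rate, label_set = label_set,
                 n_notes = as.integer(n_notes),
                 mentions_per_note = as.integer(mentions_per_note)),
            class = "synth_spec")
}

# Small bilingual oncology-flavored seed lexicon (spa = Spanish, eng =
# English); no real patient-derived text anywhere.
bilingual_lexicon <- function() {
  data.frame(
    spa = c("cáncer", "carcinoma", "tumor", "neoplasia", "mama", "pulmón",
            "hígado", "ovario", "próstata", "colon", "piel", "hueso",
            "ganglio", "axilar", "izquierda", "derecha", "ductal",
            "lobulillar", "infiltrante", "metástasis", "recidiva",
            "quimioterapia", "radioterapia", "mastectomía", "biopsia",
            "cirugía", "hormonal", "benigno", "maligno", "nódulo",
            "lesión", "margen", "cuadrante", "superior", "inferior",
            "externo", "interno", "adyuvante", "paliativo", "residual"),
    eng = c("cancer", "carcinoma", "tumor", "neoplasm", "breast", "lung",
            "liver", "ovary", "prostate", "colon", "skin", "bone",
            "node", "axillary", "left", "right", "ductal",
            "lobular", "infiltrating", "metastasis", "recurrence",
            "chemotherapy", "radiotherapy", "mastectomy", "biopsy",
            "surgery", "hormonal", "benign", "malignant", "nodule",
            "lesion", "margin", "quadrant", "upper", "lower",
            "outer", "inner", "adjuvant", "palliative", "residual"),
    stringsAsFactors = FALSE)
}

synthetic_semantic_types <- function() {
  c("Neoplastic Process", "Body Part, Organ, or Organ Component",
    "Therapeutic or Preventive Procedure", "Pharmacologic Substance",
    "Finding")
}

#' Generate a synthetic vocabulary with ground truth
#'
#' Concepts get synthetic CUIs in the reserved C9xxxxxx range (never
#' colliding with real UMLS CUIs in mixed tests), a two-token Spanish
#' surface built from the bilingual seed lexicon, its word-by-word English
#' translation, duplicate labels across fake source vocabularies,
#' homonym twins at the requested rate, and one definition each (a random
#' ~60% subset tagged NCI). A fraction `1 - p_spanish` of concepts is
#' English-only: their Spanish surface is known to the ground truth and
#' the translation dictionary but absent from the vocabulary, so they are
#' reachable only through the translation fallback.
#'
#' @param spec a [synth_spec()].
#' @return list with `records` (a `term_records` data frame), `truth`
#'   (data frame `surface, context, cui, spa_in_vocab, eng`), `
#'   translations` (named character, Spanish surface -> English surface)
#'   and `spec`.
#' @export
gen_vocab <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  lex <- bilingual_lexicon()
  sources <- c("MSH", "SNOMEDCT_US", "MDR", "ICD10CM")

  # unique two-token Spanish surfaces
  n_extra <- max(spec$n_concepts * 4L, 200L)
  i1 <- sample.int(nrow(lex), n_extra, replace = TRUE)
  i2 <- sample.int(nrow(lex), n_extra, replace = TRUE)
  ok <- i1 != i2
  pairs <- unique(data.frame(i1 = i1[ok], i2 = i2[ok]))
  # keep the Spanish and English surface inventories disjoint: a shared
  # surface across languages would make translation-fallback semantics
  # ambiguous in a way the ground-truth map cannot represent
  spa_all <- normalize_text(paste(lex$spa[pairs$i1], lex$spa[pairs$i2]))
  eng_all <- normalize_text(paste(lex$eng[pairs$i1], lex$eng[pairs$i2]))
  chosen <- integer(0)
  spa_set <- character(0); eng_set <- character(0)
  for (pi in seq_len(nrow(pairs))) {
    if (length(chosen) == spec$n_concepts) break
    if (spa_all[pi] == eng_all[pi] ||
        spa_all[pi] %in% c(spa_set, eng_set) ||
        eng_all[pi] %in% c(spa_set, eng_set)) next
    chosen <- c(chosen, pi)
    spa_set <- c(spa_set, spa_all[pi])
    eng_set <- c(eng_set, eng_all[pi])
  }
  if (length(chosen) < spec$n_concepts) {
    stop("lexicon too small for ", spec$n_concepts, " unique concepts")
  }
  pairs <- pairs[chosen, ]

  concepts <- data.frame(
    cui = sprintf("C9%06d", seq_len(spec$n_concepts)),
    spa = paste(lex$spa[pairs$i1], lex$spa[pairs$i2]),
    eng = paste(lex$eng[pairs$i1], lex$eng[pairs$i2]),
    context = sample(spec$label_set, spec$n_concepts, replace = TRUE),
    sty = sample(synthetic_semantic_types(), spec$n_concepts,
                 replace = TRUE),
    spa_in_vocab = stats::runif(spec$n_concepts) < spec$p_spanish,
    stringsAsFactors = FALSE)

  # homonym twins: same Spanish surface, new CUI, different context
  n_hom <- round(spec$homonym_rate * spec$n_concepts)
  if (n_hom > 0L) {
    base_idx <- sample(which(concepts$spa_in_vocab),
                       min(n_hom, sum(concepts$spa_in_vocab)))
    twins <- concepts[base_idx, , drop = FALSE]
    twins$cui <- sprintf("C9%06d", spec$n_concepts + seq_along(base_idx))
    twins$context <- vapply(twins$context, function(ctx)
      sample(setdiff(spec$label_set, ctx), 1L), "")
    # a distinct English label so the twins differ beyond the shared surface
    twins$eng <- paste(twins$eng, "variant")
    twins$sty <- sample(synthetic_semantic_types(), nrow(twins),
                        replace = TRUE)
    concepts <- rbind(concepts, twins)
  }

  rows <- list()
  add <- function(cui, label, lang, source, sty, def = NA_character_,
                  def_src = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cui = cui, label = label, lang = lang, source = source, tty = "PT",
      sty = sty, definition = def, def_source = def_src,
      stringsAsFactors = FALSE)
  }
  nci_def <- stats::runif(nrow(concepts)) < 0.6
  for (i in seq_len(nrow(concepts))) {
    co <- concepts[i, ]
    def <- sprintf("A synthetic concept describing %s in an oncology context.",
                   co$eng)
    def_src <- if (nci_def[i]) "NCI" else "MSH"
    add(co$cui, co$eng, "ENG", "NCI", co$sty, def, def_src)
    if (co$spa_in_vocab) {
      add(co$cui, co$spa, "SPA", sources[1 + (i %% length(sources))], co$sty)
      if (stats::runif(1) < spec$synonym_rate) {
        add(co$cui, co$spa, "SPA", sources[1 + ((i + 1) %% length(sources))],
            co$sty)
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  attr(records, "definitions") <-
    data.frame(cui = character(), definition = character(),
               def_source = character(), stringsAsFactors = FALSE)
  class(records) <- c("term_records", "data.frame")

  translations <- stats::setNames(concepts$eng, concepts$spa)
  translations <- translations[!duplicated(names(translations))]

  truth <- data.frame(surface = concepts$spa, context = concepts$context,
                      cui = concepts$cui,
                      spa_in_vocab = concepts$spa_in_vocab,
                      eng = concepts$eng, stringsAsFactors = FALSE)
  list(records = records, truth = truth, translations = translations,
       spec = spec)
}

# one-character deletion typo inside the longest token (>= 4 chars)
apply_typo <- function(text) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  cand <- which(nchar(toks) >= 4L)
  if (length(cand) == 0L) return(text)
  ti <- cand[which.max(nchar(toks[cand]))]
  w <- toks[ti]
  pos <- sample(2:(nchar(w) - 1L), 1L)
  toks[ti] <- paste0(substr(w, 1L, pos - 1L), substr(w, pos + 1L, nchar(w)))
  paste(toks, collapse = " ")
}

#' Generate synthetic notes, gold benchmark and gazetteer lexicon
#'
#' Plants known mentions into short Spanish clinical-style sentences.
#' Gold records are the unique (mention text, context, CUI set) triples of
#' the planted mentions; the gazetteer lexicon maps each planted surface
#' to its context label (for a homonym surface, the label of the first
#' planted twin — corpora meant for the NER path should be generated with
#' `homonym_rate = 0`). Mention offsets into each note are recorded.
#'
#' @param vocab a [gen_vocab()] result.
#' @param spec a [synth_spec()]; defaults to the one inside `vocab`.
#' @return list with `notes` (list of `clinical_note`), `gold` (data
#'   frame `text, context` + list column `cuis`), `lexicon` (named
#'   character surface -> label), `mentions` (data frame with note ids,
#'   offsets and intended CUI) and `spec`.
#' @export
gen_notes <- function(vocab, spec = vocab$spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 1L)
  truth <- vocab$truth
  in_vocab <- truth[truth$spa_in_vocab, , drop = FALSE]
  oov <- truth[!truth$spa_in_vocab, , drop = FALSE]
  templates <- c("Paciente diagnosticado con %s.",
                 "Se observa %s en la exploración.",
                 "Tratamiento indicado: %s.",
                 "Hallazgo compatible con %s.")
  notes <- list()
  mention_rows <- list()
  for (ni in seq_len(spec$n_notes)) {
    sents <- character()
    for (mi in seq_len(spec$mentions_per_note)) {
      use_oov <- nrow(oov) > 0L && stats::runif(1) < spec$oov_rate
      src <- if (use_oov) oov else in_vocab
      ci <- sample.int(nrow(src), 1L)
      mention <- src$surface[ci]
      if (stats::runif(1) < spec$typo_rate) mention <- apply_typo(mention)
      tpl <- templates[1 + ((ni + mi) %% length(templates))]
      sent <- sprintf(tpl, mention)
      m_start <- regexpr(mention, sent, fixed = TRUE)
      offset <- sum(nchar(sents)) + length(sents) + m_start - 1L
      sents <- c(sents, sent)
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        note_id = sprintf("note-%03d", ni), text = mention,
        context = src$context[ci], cui = src$cui[ci],
        start = as.integer(offset), end = as.integer(offset + nchar(mention)),
        stringsAsFactors = FALSE)
    }
    notes[[ni]] <- clinical_note(paste(sents, collapse = " "),
                                 sprintf("note-%03d", ni))
  }
  mentions <- do.call(rbind, mention_rows)

  key <- paste(normalize_text(mentions$text), mentions$context, sep = "\r")
  first <- !duplicated(key)
  gold <- mentions[first, c("text", "context"), drop = FALSE]
  gold$cuis <- lapply(which(first), function(i) mentions$cui[i])
  rownames(gold) <- NULL

  lex_first <- !duplicated(normalize_text(mentions$text))
  lexicon <- stats::setNames(mentions$context[lex_first],
                             mentions$text[lex_first])
  list(notes = notes, gold = gold, lexicon = lexicon, mentions = mentions,
       spec = spec)
}

#' Deterministic mock LLM clients
#'
#' Three behaviours behind the standard [llm_client()] contract:
#' \describe{
#'   \item{oracle}{answers a disambiguation prompt with the ground-truth
#'     CUI(s) for the (mention, context) pair when offered; otherwise
#'     declares the candidates inadequate and supplies the fixture
#'     translation. Translation prompts are answered from the fixture
#'     dictionary (terms not in it are returned unchanged).}
#'   \item{adversarial}{always declares the candidates inadequate (with
#'     the fixture translation when available).}
#'   \item{scripted}{replays a canned response list (see
#'     [scripted_llm()]).}
#' }
#'
#' @param mode `"oracle"`, `"adversarial"` or `"scripted"`.
#' @param truth truth data frame (`surface, context, cui`) — required for
#'   oracle mode.
#' @param translations named character vector, Spanish term -> English.
#' @param script responses for scripted mode.
#' @return an [llm_client()].
#' @export
mock_llm <- function(mode = c("oracle", "adversarial", "scripted"),
                     truth = NULL, translations = character(),
                     script = NULL) {
  mode <- match.arg(mode)
  if (mode == "scripted") {
    if (is.null(script)) stop("scripted mode needs a response script")
    return(scripted_llm(script))
  }
  if (mode == "oracle" && is.null(truth)) {
    stop("oracle mode needs the ground-truth map")
  }
  tr_keys <- normalize_text(names(translations))
  lookup_translation <- function(term) {
    tn <- normalize_text(term)
    i <- match(tn, tr_keys)
    if (!is.na(i)) return(unname(translations[i]))
    if (tn %in% normalize_text(unname(translations))) return(term)
    term
  }
  truth_key <- if (!is.null(truth)) {
    paste(normalize_text(truth$surface), truth$context, sep = "\r")
  }
  complete <- function(prompt) {
    if (grepl("^Translate", prompt)) {
      term <- stringi::stri_match_first_regex(prompt, "TERM:\\s*(.+)")[1, 2]
      return(list(text = paste0("TRANSLATION: ",
                                lookup_translation(trimws(term)))))
    }
    surface <- trimws(stringi::stri_match_first_regex(
      prompt, "Entity:\\s*([^\\n]+)")[1, 2])
    context <- trimws(stringi::stri_match_first_regex(
      prompt, "Context:\\s*([^\\n]+)")[1, 2])
    offered <- unique(stringi::stri_extract_all_regex(
      prompt, "CUI:\\s*(C\\d+)")[[1]])
    offered <- stringi::stri_replace_first_regex(offered, "CUI:\\s*", "")
    if (mode == "oracle") {
      gold <- truth$cui[truth_key ==
                          paste(normalize_text(surface), context, sep = "\r")]
      sel <- intersect(offered, gold)
      if (length(sel)) {
        return(list(text = paste0(
          "The context label matches this concept's definition.\n",
          "ANSWER: ", paste(sel, collapse = " "))))
      }
    }
    tr <- lookup_translation(surface)
    list(text = paste0("None of the offered concepts fits the mention.\n",
                       "ANSWER: NONE | TRANSLATION: ", tr))
  }
  llm_client(complete, name = paste0("mock-", mode))
}
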
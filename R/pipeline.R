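#' Pipeline configuration
#'
#' Bundles every tunable of the linking pipeline. The defaults are the
#' best-performing configuration of the method's case study: boosted
#' multi-match retrieval, similarity threshold 0.96, 15 candidates,
#' chain-of-thought prompting, Spanish-first search with a single
#' translate-to-English retry round.
#'
#' @param q_type query type (see [build_query()]).
#' @param theta_sim similarity threshold in \[0, 1\].
#' @param k number of candidates retrieved.
#' @param prompt_style prompt style (`"CoT"`, `"FewShot"`, `"ZeroShot"`).
#' @param lang language constraint for Exact/Basic_Fuzzy queries
#'   (`"SPA"`, `"ENG"` or `"any"`).
#' @param lang_priority search order across translation rounds.
#' @param max_translation_rounds retry bound after the initial pass
#'   (default 1: one Spanish pass, then at most one English pass).
#' @param boost_words,boost_factor boosted-query settings.
#' @param seed RNG seed recorded with the run.
#' @param cache enable the in-process (surface, label, config) cache.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(q_type = "Multi_match_boosted",
                            theta_sim = 0.96, k = 15L,
                            prompt_style = "CoT", lang = "any",
                            lang_priority = c("SPA", "ENG"),
                            max_translation_rounds = 1L,
                            boost_words = default_boost_words(),
                            boost_factor = 2.0, seed = 42L,
                            cache = FALSE) {
  stopifnot(theta_sim >= 0, theta_sim <= 1, k >= 1L,
            max_translation_rounds >= 0L)
  structure(list(q_type = q_type, theta_sim = theta_sim, k = as.integer(k),
                 prompt_style = prompt_style, lang = lang,
                 lang_priority = lang_priority,
                 max_translation_rounds = as.integer(max_translation_rounds),
                 boost_words = boost_words, boost_factor = boost_factor,
                 seed = as.integer(seed), cache = isTRUE(cache)),
            class = "pipeline_config")
}

config_hash <- function(config, index = NULL) {
  fnv1a(paste(stable_serialize(unclass(config)),
              if (!is.null(index)) index$build_hash else "", sep = "#"))
}

#' Create an in-process link cache
#'
#' Once a (mention, context label) pair has been linked under a given
#' configuration, the result can be replayed without re-querying the index
#' or the LLM. Keys include the config/index hash, so changing either
#' invalidates the cache.
#' @return a `link_cache` environment.
#' @export
new_link_cache <- function() {
  structure(new.env(parent = emptyenv()), class = "link_cache")
}

#' Link one recognized entity to vocabulary concepts
#'
#' The full per-entity flow: search the mention (Spanish first), filter by
#' similarity, decide. A unique confident concept links directly with no
#' LLM involvement; an ambiguous set goes to the LLM disambiguator; when
#' there is no candidate, or the LLM finds the candidates inadequate, the
#' term is translated into English and the search repeated, up to
#' `max_translation_rounds` extra passes. An entity that survives all
#' rounds unresolved is UNLINKED (a result, not an error).
#'
#' @param entity a one-row entity data frame (see [recognize()]) or a list
#'   with `surface` and `label`.
#' @param index a `vocab_index`.
#' @param config a [pipeline_config()].
#' @param client an [llm_client()]; only consulted on AMBIGUOUS decisions
#'   and for translations.
#' @param cache optional [new_link_cache()].
#' @return a `linked_entity`: list with `surface`, `label`, `cuis`,
#'   `status` (`LINKED_DIRECT`, `LINKED_LLM`, `LINKED_AFTER_TRANSLATION`,
#'   `UNLINKED`), `translation`, `ranked_cuis` (final CUIs first, then
#'   remaining candidates in retrieval order), `llm_calls`, `trace`,
#'   `cache_hit`.
#' @export
link_entity <- function(entity, index, config = pipeline_config(),
                        client = NULL, cache = NULL) {
  surf <- entity$surface_expanded %||% entity$surface
  if (is.data.frame(entity)) surf <- surf[1]
  label <- if (is.data.frame(entity)) entity$label[1] else entity$label
  chash <- config_hash(config, index)
  key <- paste(normalize_text(surf), label, chash, sep = "\r")
  if (!is.null(cache) && config$cache && !is.null(cache[[key]])) {
    hitres <- cache[[key]]
    hitres$cache_hit <- TRUE
    hitres$llm_calls <- list(disambiguation = 0L, translation = 0L,
                             prompt_tokens = 0L, completion_tokens = 0L)
    return(hitres)
  }

  term <- surf
  translation_used <- NULL
  status <- NULL
  cuis <- character()
  trace <- list()
  n_dis <- 0L; n_tr <- 0L; p_tok <- 0L; c_tok <- 0L
  seen_cuis <- character()

  for (round in 0:config$max_translation_rounds) {
    lang_override <- NULL
    if (round > 0L && (config$q_type == "Multi_match_SPA" ||
                       identical(config$lang, "SPA"))) {
      lang_override <- "ENG"
    }
    q <- build_query(term, config, lang_override = lang_override)
    cands <- search_index(index, q)
    filt <- filter_candidates(cands, term, config$theta_sim)
    dec <- decide(filt)
    seen_cuis <- c(seen_cuis, filt$by_cui$cui)
    trace[[length(trace) + 1L]] <- list(
      round = round, term = term, q_type = q$q_type, lang = q$lang,
      n_candidates = nrow(cands), branch = dec$branch,
      low_confidence = dec$low_confidence,
      candidates = filt$by_cui[, intersect(
        c("cui", "label", "retrieval_score", "similarity"),
        names(filt$by_cui)), drop = FALSE])

    if (dec$branch == "DIRECT_LINK") {
      status <- if (round == 0L) "LINKED_DIRECT" else "LINKED_AFTER_TRANSLATION"
      cuis <- dec$cui
      break
    }

    translation <- NULL
    if (dec$branch == "AMBIGUOUS") {
      if (is.null(client)) {
        stop("AMBIGUOUS decision for '", surf, "' but no LLM client given")
      }
      res <- disambiguate(client, term, label, dec$candidates,
                          prompt_spec(config$prompt_style), index)
      n_dis <- n_dis + 1L
      p_tok <- p_tok + res$token_usage$prompt_tokens
      c_tok <- c_tok + res$token_usage$completion_tokens
      trace[[length(trace)]]$llm_outcome <- res$outcome
      if (res$outcome == "SELECTED") {
        status <- if (round == 0L) "LINKED_LLM" else "LINKED_AFTER_TRANSLATION"
        cuis <- res$selected_cuis
        break
      }
      translation <- res$translation
    }

    if (round < config$max_translation_rounds) {
      if (is.null(translation)) {
        if (is.null(client)) break
        tr <- translate_term(client, term)
        n_tr <- n_tr + 1L
        p_tok <- p_tok + tr$token_usage$prompt_tokens
        c_tok <- c_tok + tr$token_usage$completion_tokens
        translation <- tr$translation
      }
      if (is.null(translation) ||
          normalize_text(translation) == normalize_text(term)) {
        if (is.null(translation)) break
      }
      translation_used <- translation
      term <- translation
    }
  }
  if (is.null(status)) status <- "UNLINKED"

  out <- structure(list(
    surface = surf, label = label, cuis = cuis, status = status,
    translation = translation_used,
    ranked_cuis = unique(c(cuis, seen_cuis)),
    llm_calls = list(disambiguation = n_dis, translation = n_tr,
                     prompt_tokens = p_tok, completion_tokens = c_tok),
    trace = trace, cache_hit = FALSE
  ), class = "linked_entity")
  if (!is.null(cache) && config$cache) cache[[key]] <- out
  out
}

#' @export
print.linked_entity <- function(x, ...) {
  cat(sprintf("<linked_entity> '%s' [%s] -> %s (%s)\n", x$surface, x$label,
              if (length(x$cuis)) paste(x$cuis, collapse = ", ") else "-",
              x$status))
  invisible(x)
}

#' Recognize and link all entities of a note
#'
#' Runs NER, then links each recognized entity independently, preserving
#' order. Per-entity failures are isolated: the failing entity is reported
#' UNLINKED with the error message in its trace and processing continues.
#'
#' @inheritParams link_entity
#' @param note a [clinical_note()] or string.
#' @param recognizer recognizer function (see [gazetteer_recognizer()]).
#' @param acronym_dict passed to [recognize()].
#' @return list of `linked_entity` objects (entity metadata attached).
#' @export
link_note <- function(note, index, config = pipeline_config(),
                      client = NULL, recognizer, cache = NULL,
                      acronym_dict = default_acronyms()) {
  if (is.character(note)) note <- clinical_note(note)
  ents <- recognize(note, recognizer, acronym_dict)
  out <- vector("list", nrow(ents))
  for (i in seq_len(nrow(ents))) {
    ent <- ents[i, , drop = FALSE]
    le <- tryCatch(
      link_entity(ent, index, config, client, cache),
      error = function(e) {
        structure(list(surface = ent$surface_expanded, label = ent$label,
                       cuis = character(), status = "UNLINKED",
                       translation = NULL, ranked_cuis = character(),
                       llm_calls = list(disambiguation = 0L, translation = 0L,
                                        prompt_tokens = 0L,
                                        completion_tokens = 0L),
                       trace = list(error = conditionMessage(e)),
                       cache_hit = FALSE),
                  class = "linked_entity")
      })
    le$note_id <- note$note_id
    le$span <- c(ent$start, ent$end)
    out[[i]] <- le
  }
  out
}

#' Run the pipeline over a corpus
#'
#' @param corpus list of [clinical_note()]s, a list of `list(note_id,
#'   text)` records, or the path of a JSON-lines file with those fields.
#' @inheritParams link_note
#' @param out optional path: linked entities are written there as
#'   JSON-lines `{note_id, surface, label, cuis, ranked_cuis, status,
#'   translation}` — byte-identical across runs with the same seed and
#'   deterministic clients.
#' @return a `pipeline_run`: list with `results` (list of `linked_entity`),
#'   `records` (the flat output records) and `report` (status counts, LLM
#'   call and token totals, wall time, resolved config, index hash).
#' @export
run_pipeline <- function(corpus, index, config = pipeline_config(),
                         client = NULL, recognizer,
                         acronym_dict = default_acronyms(), out = NULL) {
  t0 <- Sys.time()
  if (is.character(corpus) && length(corpus) == 1L) {
    corpus <- read_jsonl(corpus)
  }
  notes <- lapply(corpus, function(n) {
    if (inherits(n, "clinical_note")) n
    else clinical_note(n$text, n$note_id %||% "note")
  })
  build_query("startup-config-check", config)  # fail fast on a bad q_type
  set.seed(config$seed)
  cache <- if (config$cache) new_link_cache() else NULL
  results <- list()
  for (nt in notes) {
    results <- c(results, link_note(nt, index, config, client, recognizer,
                                    cache, acronym_dict))
  }
  records <- lapply(results, function(le) {
    list(note_id = le$note_id, surface = le$surface, label = le$label,
         cuis = I(le$cuis), ranked_cuis = I(le$ranked_cuis),
         status = le$status,
         translation = le$translation %||% NA_character_)
  })
  statuses <- vapply(results, `[[`, "", "status")
  report <- list(
    n_notes = length(notes),
    n_entities = length(results),
    status_counts = as.list(table(factor(statuses, levels = c(
      "LINKED_DIRECT", "LINKED_LLM", "LINKED_AFTER_TRANSLATION",
      "UNLINKED")))),
    llm_disambiguation_calls = sum(vapply(results, function(x)
      x$llm_calls$disambiguation, 0L)),
    llm_translation_calls = sum(vapply(results, function(x)
      x$llm_calls$translation, 0L)),
    prompt_tokens = sum(vapply(results, function(x)
      x$llm_calls$prompt_tokens, 0L)),
    completion_tokens = sum(vapply(results, function(x)
      x$llm_calls$completion_tokens, 0L)),
    cache_hits = sum(vapply(results, function(x) isTRUE(x$cache_hit), TRUE)),
    config = unclass(config),
    index_hash = index$build_hash,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out)) write_jsonl(records, out)
  structure(list(results = results, records = records, report = report),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<pipeline_run> %d notes, %d entities\n", r$n_notes,
              r$n_entities))
  for (s in names(r$status_counts)) {
    cat(sprintf("  %-25s %d\n", s, r$status_counts[[s]]))
  }
  cat(sprintf("  LLM calls: %d disambiguation, %d translation\n",
              r$llm_disambiguation_calls, r$llm_translation_calls))
  invisible(x)
}
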
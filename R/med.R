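#' Select the preferred definition of a concept
#'
#' UMLS concepts usually carry several definitions from different source
#' vocabularies. For prompting we prefer the NCI (National Cancer
#' Institute) definition — an authoritative source for cancer concepts —
#' then fall back through a documented source-priority list, then to the
#' first remaining definition; concepts with no definition get a
#' placeholder.
#'
#' @param concept_entry one entry of a `concept_table`.
#' @param priority source priority order; NCI first by default.
#' @return list `(definition, source)`.
#' @export
select_definition <- function(concept_entry,
                              priority = c("NCI", "MSH", "SNOMEDCT_US",
                                           "SNOMEDCT", "ICD10CM", "HPO")) {
  defs <- concept_entry$definitions
  if (is.null(defs) || nrow(defs) == 0L) {
    return(list(definition = "no definition available", source = ""))
  }
  for (src in priority) {
    hit <- which(defs$def_source == src)
    if (length(hit)) {
      return(list(definition = defs$definition[hit[1]], source = src))
    }
  }
  list(definition = defs$definition[1], source = defs$def_source[1])
}

#' Prompt specification
#' @param style one of `"CoT"` (chain-of-thought, default), `"FewShot"`,
#'   `"ZeroShot"`.
#' @param max_tokens,temperature generation settings passed to the client
#'   (defaults 512 and 0 — deterministic decoding).
#' @param exemplars few-shot exemplar block (FewShot only); two shipped
#'   synthetic exemplars by default.
#' @return a `prompt_spec` object.
#' @export
prompt_spec <- function(style = c("CoT", "FewShot", "ZeroShot"),
                        max_tokens = 512L, temperature = 0,
                        exemplars = NULL) {
  style <- match.arg(style)
  structure(list(style = style, max_tokens = as.integer(max_tokens),
                 temperature = temperature,
                 exemplars = exemplars %||% default_exemplars()),
            class = "prompt_spec")
}

default_exemplars <- function() {
  paste(
    "Example 1:",
    "Entity: quimio | Context: Treatment drug",
    "Candidate: CUI C9100001, a drug-based cancer treatment.",
    "Reasoning: the mention is a colloquial form of chemotherapy,",
    "which matches the candidate's definition.",
    "ANSWER: C9100001",
    "",
    "Example 2:",
    "Entity: margen | Context: Surgery",
    "Candidate: CUI C9100002, a typographical sign.",
    "Reasoning: the candidate is unrelated to surgical margins;",
    "no offered concept is suitable.",
    "ANSWER: NONE | TRANSLATION: surgical margin",
    sep = "\n")
}

#' Render a disambiguation prompt
#'
#' Lists the mention, its context label, and every candidate with its CUI,
#' label, semantic group and preferred definition (NCI-first, see
#' [select_definition()]). The chain-of-thought style instructs the model
#' to reason step by step, say whether a suitable CUI exists and, if not,
#' to provide an English translation of the term. The final line of the
#' response must follow the machine-readable contract
#' `ANSWER: <CUIs>` or `ANSWER: NONE | TRANSLATION: <term>`.
#' Rendering is deterministic: identical inputs give byte-identical text.
#'
#' @param surface the mention text.
#' @param context_label its context label from the annotation scheme.
#' @param candidates data frame with at least `cui`, `label`,
#'   `semantic_type` (one row per CUI; see [decide()]).
#' @param spec a [prompt_spec()].
#' @param index a `vocab_index` used to look up definitions; optional —
#'   without it candidates must carry a `definition` column.
#' @return the prompt text (single string).
#' @export
build_prompt <- function(surface, context_label, candidates,
                         spec = prompt_spec(), index = NULL) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  if (any(is.na(candidates$cui)) || any(!nzchar(candidates$cui))) {
    stop("candidate without a CUI")
  }
  defs <- vapply(seq_len(nrow(candidates)), function(i) {
    if (!is.null(candidates$definition) &&
        !is.na(candidates$definition[i])) {
      return(candidates$definition[i])
    }
    if (!is.null(index)) {
      entry <- index$concepts[[candidates$cui[i]]]
      if (!is.null(entry)) return(select_definition(entry)$definition)
    }
    "no definition available"
  }, "")
  cand_lines <- vapply(seq_len(nrow(candidates)), function(i) {
    sprintf("%d. CUI: %s | Label: %s | Semantic group: %s | Definition: %s",
            i, candidates$cui[i], candidates$label[i],
            if (nzchar(candidates$semantic_type[i]))
              candidates$semantic_type[i] else "unknown",
            defs[i])
  }, "")

  header <- paste0(
    "You are a clinical terminology expert linking Spanish oncology ",
    "mentions to concepts in a medical vocabulary.")
  task <- paste0(
    "Entity: ", surface, "\n",
    "Context: ", context_label, "\n",
    "Candidates:\n", paste(cand_lines, collapse = "\n"))
  contract <- paste0(
    "Finish with exactly one line:\n",
    "ANSWER: <the chosen CUIs separated by spaces>\n",
    "or, when none is suitable,\n",
    "ANSWER: NONE | TRANSLATION: <the English translation of the term>")

  body <- switch(spec$style,
    CoT = paste(header,
                "Think step by step: compare the mention and its context",
                "with each candidate's label, semantic group and",
                "definition, state your reasoning, and say whether a",
                "suitable CUI exists; if it does not, provide an English",
                "translation of the term.",
                task, contract, sep = "\n\n"),
    FewShot = paste(header, spec$exemplars, task, contract, sep = "\n\n"),
    ZeroShot = paste(header, task, contract, sep = "\n\n"))
  body
}

#' Count whitespace-delimited tokens
#' @param text character vector.
#' @return integer count of tokens over all elements.
#' @export
count_tokens <- function(text) {
  sum(vapply(stringi::stri_split_regex(text, "\\s+", omit_empty = TRUE),
             length, 0L))
}

#' Parse an LLM disambiguation response
#'
#' Primary route: the machine-readable final `ANSWER:` line. Fallback:
#' pattern extraction of CUIs (`C` + digits) anywhere in the text. CUIs
#' not among the offered candidates are discarded — a response naming only
#' non-offered CUIs is INADEQUATE. A declared `NONE` with a
#' `TRANSLATION:` yields INADEQUATE plus the translation; unparseable text
#' yields INADEQUATE without translation. Total by design: never errors.
#'
#' @param raw response text.
#' @param offered_cuis character vector of candidate CUIs in the prompt.
#' @return a `disambiguation_result`: list with `outcome`
#'   (`"SELECTED" | "INADEQUATE"`), `selected_cuis`, `translation`,
#'   `rationale` (the raw text).
#' @export
parse_response <- function(raw, offered_cuis) {
  raw <- paste(as.character(raw), collapse = "\n")
  res <- function(outcome, cuis = character(), translation = NULL) {
    structure(list(outcome = outcome, selected_cuis = cuis,
                   translation = translation, rationale = raw),
              class = "disambiguation_result")
  }
  get_translation <- function(text) {
    m <- stringi::stri_match_first_regex(
      text, "TRANSLATION:\\s*([^\\n|]+)", case_insensitive = TRUE)
    tr <- trimws(m[1, 2])
    if (is.na(tr) || !nzchar(tr)) NULL else tr
  }
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  ans <- grep("^\\s*ANSWER\\s*:", lines, ignore.case = TRUE, value = TRUE)
  target <- if (length(ans)) ans[length(ans)] else raw
  if (length(ans) &&
      grepl("\\bNONE\\b", target, ignore.case = TRUE)) {
    return(res("INADEQUATE", translation = get_translation(raw)))
  }
  found <- unique(stringi::stri_extract_all_regex(target, "C\\d+")[[1]])
  found <- found[!is.na(found)]
  kept <- intersect(found, offered_cuis)
  if (length(kept)) return(res("SELECTED", cuis = kept))
  if (grepl("no suitable", raw, ignore.case = TRUE) ||
      grepl("\\bNONE\\b", raw)) {
    return(res("INADEQUATE", translation = get_translation(raw)))
  }
  res("INADEQUATE", translation = get_translation(raw))
}

#' Construct an LLM client
#'
#' The disambiguator is model-agnostic: any client exposing
#' `complete(prompt)` returning `list(text = <string>)` can be plugged in
#' (deterministic mocks for testing — see [mock_llm()] — or an adapter
#' around a hosted API).
#'
#' @param complete function `(prompt) -> list(text)`.
#' @param name client name used in traces.
#' @return an `llm_client`.
#' @export
llm_client <- function(complete, name = "custom") {
  stopifnot(is.function(complete))
  structure(list(complete = complete, name = name), class = "llm_client")
}

#' Scripted LLM client
#'
#' Replays canned responses in order; errors when the script is exhausted.
#' @param responses character vector of responses.
#' @return an `llm_client`.
#' @export
scripted_llm <- function(responses) {
  i <- 0L
  llm_client(function(prompt) {
    i <<- i + 1L
    if (i > length(responses)) stop("scripted LLM: response script exhausted")
    list(text = responses[i])
  }, name = "scripted")
}

# One guarded client call with bounded retries.
call_llm <- function(client, prompt, max_retries = 3L) {
  for (attempt in seq_len(max_retries)) {
    out <- tryCatch(client$complete(prompt), error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last <- out
  }
  NULL
}

#' Disambiguate an ambiguous candidate set with an LLM
#'
#' Renders the prompt, makes exactly one client call (with up to
#' `max_retries` attempts on transport failure, after which the result is
#' INADEQUATE without translation), and parses the response. Token usage
#' (whitespace-token counts of prompt and response) is attached.
#'
#' @param client an [llm_client()].
#' @param surface,context_label the mention and its context label.
#' @param candidates candidate data frame (one row per CUI).
#' @param spec a [prompt_spec()].
#' @param index optional `vocab_index` for definition lookup.
#' @param max_retries transport retry bound (default 3).
#' @return a `disambiguation_result` with a `token_usage` element.
#' @export
disambiguate <- function(client, surface, context_label, candidates,
                         spec = prompt_spec(), index = NULL,
                         max_retries = 3L) {
  stopifnot(inherits(client, "llm_client"))
  prompt <- build_prompt(surface, context_label, candidates, spec, index)
  out <- call_llm(client, prompt, max_retries)
  if (is.null(out)) {
    result <- structure(list(outcome = "INADEQUATE",
                             selected_cuis = character(),
                             translation = NULL,
                             rationale = "client transport failure"),
                        class = "disambiguation_result")
  } else {
    result <- parse_response(out$text, candidates$cui)
  }
  result$token_usage <- list(
    prompt_tokens = count_tokens(prompt),
    completion_tokens = if (is.null(out)) 0L else count_tokens(out$text))
  result$prompt <- prompt
  result
}

#' Translate a term into English via the LLM client
#'
#' Used by the fallback loop: when a Spanish mention cannot be linked, the
#' term is translated and the search repeated on the English form.
#'
#' @param client an [llm_client()].
#' @param term non-empty term to translate.
#' @param max_retries transport retry bound.
#' @return list `(translation, token_usage)`; `translation` is `NULL` if
#'   the client fails or returns nothing usable.
#' @export
translate_term <- function(client, term, max_retries = 3L) {
  stopifnot(nzchar(term))
  prompt <- paste0(
    "Translate the following Spanish medical term into English.\n",
    "TERM: ", term, "\n",
    "Reply with exactly one line: TRANSLATION: <English term>")
  out <- call_llm(client, prompt, max_retries)
  tr <- NULL
  if (!is.null(out)) {
    m <- stringi::stri_match_first_regex(
      out$text, "TRANSLATION:\\s*([^\\n|]+)", case_insensitive = TRUE)
    cand <- trimws(m[1, 2])
    if (!is.na(cand) && nzchar(cand)) tr <- cand
  }
  list(translation = tr,
       token_usage = list(
         prompt_tokens = count_tokens(prompt),
         completion_tokens = if (is.null(out)) 0L else count_tokens(out$text)))
}
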
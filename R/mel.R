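#' Build a retrieval query for a mention
#'
#' Five query types of increasing fuzziness are supported, mirroring the
#' search behaviours the linker can be configured with:
#' \describe{
#'   \item{Exact}{only documents whose normalized label equals the
#'     normalized mention.}
#'   \item{Basic_Fuzzy}{every query token must match a label token within
#'     a small edit-distance budget (1 edit for tokens of length <= 5,
#'     2 otherwise).}
#'   \item{Multi_match_SPA}{highest fuzziness — any query token may match
#'     any of the label/synonyms/definition fields — restricted to
#'     Spanish-language labels.}
#'   \item{Multi_match}{as Multi_match_SPA but over every language.}
#'   \item{Multi_match_boosted}{as Multi_match, with candidates whose
#'     label contains a boost word (a configurable cancer lexicon by
#'     default) multiplied by `boost_factor`.}
#' }
#'
#' @param text the mention surface (an entity's text).
#' @param config a [pipeline_config()] (or any list with `q_type`, `k`,
#'   `lang`, `boost_words`, `boost_factor`).
#' @param lang_override optional language constraint replacing the
#'   config-derived one (used by the pipeline on translated retries).
#' @return a `mel_query` object.
#' @export
build_query <- function(text, config = pipeline_config(),
                        lang_override = NULL) {
  q_types <- c("Exact", "Basic_Fuzzy", "Multi_match_SPA", "Multi_match",
               "Multi_match_boosted")
  if (!config$q_type %in% q_types) {
    stop("unknown q_type: ", config$q_type,
         " (expected one of ", paste(q_types, collapse = ", "), ")")
  }
  lang <- switch(config$q_type,
    Multi_match_SPA = "SPA",
    Multi_match = "any",
    Multi_match_boosted = "any",
    config$lang %||% "any")
  if (!is.null(lang_override)) lang <- lang_override
  norm <- normalize_text(text)
  structure(list(
    text = text,
    text_norm = norm,
    tokens = unique(tokenize_text(norm)[[1]]),
    q_type = config$q_type,
    k = config$k %||% 15L,
    lang = lang,
    boost_words = if (config$q_type == "Multi_match_boosted")
      normalize_text(config$boost_words %||% default_boost_words()) else character(),
    boost_factor = config$boost_factor %||% 2.0
  ), class = "mel_query")
}

#' Default boost lexicon: cancer-related terms prioritized in boosted queries
#' @return character vector of boost words.
#' @export
default_boost_words <- function() {
  c("cáncer", "cancer", "carcinoma", "tumor", "neoplasia", "maligno")
}

#' Search the index for candidate terms
#'
#' Retrieves up to `k` candidate (CUI, label) documents for the query,
#' scored by BM25 (see [build_index()]) under the query type's matching
#' semantics, sorted by retrieval score, then linking score, then CUI.
#' Multi-match queries score best-field: the maximum of the label,
#' synonyms and (down-weighted) definition field scores.
#'
#' @param index a `vocab_index`.
#' @param query a `mel_query`.
#' @return data frame of candidates: `cui, label, label_norm, lang,
#'   semantic_type, linking_score, retrieval_score` (possibly 0 rows).
#' @export
search_index <- function(index, query) {
  stopifnot(inherits(index, "vocab_index"), inherits(query, "mel_query"))
  docs <- index$docs
  keep <- rep(TRUE, nrow(docs))
  if (query$lang != "any") keep <- docs$lang == query$lang

  p <- index$params
  n_docs <- nrow(docs)
  score <- rep(0, n_docs)
  hit <- rep(FALSE, n_docs)

  if (query$q_type == "Exact") {
    hit <- keep & docs$label_norm == query$text_norm
    if (any(hit)) {
      score[hit] <- field_scores_exact(index, query$tokens, which(hit))
    }
  } else if (query$q_type == "Basic_Fuzzy") {
    if (length(query$tokens)) {
      fm <- lapply(query$tokens, function(t)
        fuzzy_tf_field(index, t, "tok_label"))
      matched_all <- Reduce(`&`, lapply(fm, function(x) x$tf > 0))
      hit <- keep & matched_all
      if (any(hit)) {
        idx_hit <- which(hit)
        for (x in fm) {
          dfreq <- sum(x$tf > 0)
          score[idx_hit] <- score[idx_hit] + vapply(idx_hit, function(d)
            bm25_weight(x$tf[d], dfreq, n_docs,
                        index$field_stats$label$lens[d],
                        index$field_stats$label$avgdl,
                        p$k1, p$b, p$delta), 0)
        }
      }
    }
  } else {
    # Multi_match family: OR semantics, fuzzy per-token, best-field score
    fields <- c(label = "tok_label", synonyms = "tok_synonyms",
                definition = "tok_definition")
    weights <- c(label = 1, synonyms = 1,
                 definition = p$definition_weight)
    fscores <- matrix(0, nrow = n_docs, ncol = length(fields),
                      dimnames = list(NULL, names(fields)))
    any_match <- rep(FALSE, n_docs)
    for (fi in seq_along(fields)) {
      fname <- names(fields)[fi]
      st <- index$field_stats[[fname]]
      for (t in query$tokens) {
        x <- fuzzy_tf_field(index, t, fields[[fi]])
        dfreq <- sum(x$tf > 0)
        if (dfreq == 0) next
        any_match <- any_match | x$tf > 0
        nz <- which(x$tf > 0)
        fscores[nz, fi] <- fscores[nz, fi] + vapply(nz, function(d)
          bm25_weight(x$tf[d], dfreq, n_docs, st$lens[d], st$avgdl,
                      p$k1, p$b, p$delta), 0)
      }
      fscores[, fi] <- fscores[, fi] * weights[fi]
    }
    hit <- keep & any_match
    score[hit] <- apply(fscores[hit, , drop = FALSE], 1, max)
    if (query$q_type == "Multi_match_boosted" && length(query$boost_words)) {
      boosted <- hit & vapply(docs$tok_label, function(tk)
        any(tk %in% query$boost_words), TRUE)
      score[boosted] <- score[boosted] * query$boost_factor
    }
  }

  res <- docs[hit, c("cui", "label", "label_norm", "lang", "sty",
                     "linking_score"), drop = FALSE]
  names(res)[names(res) == "sty"] <- "semantic_type"
  res$retrieval_score <- score[hit]
  ord <- order(-res$retrieval_score, -res$linking_score, res$cui,
               res$label_norm)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, query$k)
}

# Exact-token BM25 score on the label field for the given doc indices.
field_scores_exact <- function(index, tokens, doc_idx) {
  st <- index$field_stats$label
  p <- index$params
  n_docs <- nrow(index$docs)
  vapply(doc_idx, function(d) {
    tk <- index$docs$tok_label[[d]]
    s <- 0
    for (t in tokens) {
      tf <- sum(tk == t)
      dfreq <- unname(st$df[t])
      if (is.na(dfreq)) dfreq <- 0L
      s <- s + bm25_weight(tf, dfreq, n_docs, st$lens[d], st$avgdl,
                           p$k1, p$b, p$delta)
    }
    s
  }, 0)
}

# Per-document fuzzy term frequency of query token `t` in one field:
# the count of field tokens within the edit budget. Matching is done once
# against the field's vocabulary, then mapped onto documents.
fuzzy_tf_field <- function(index, t, field_col) {
  st <- switch(field_col, tok_label = index$field_stats$label,
               tok_synonyms = index$field_stats$synonyms,
               tok_definition = index$field_stats$definition)
  vocab <- names(st$df)
  if (length(vocab) == 0L) {
    return(list(tf = rep(0L, nrow(index$docs))))
  }
  ok <- vocab[fuzzy_hits(t, vocab)]
  tf <- vapply(index$docs[[field_col]], function(tk)
    sum(tk %in% ok), 0L)
  list(tf = tf)
}

#' Filter retrieved candidates by similarity to the mention
#'
#' Each candidate is annotated with the Ratcliff-Obershelp similarity
#' between the (normalized) mention and its matched label. Candidates with
#' similarity >= `theta_sim` form the *confident* set. When nothing is
#' confident, the full retrieved set is passed onward flagged as
#' low-confidence, so the disambiguation stage can still reason over it —
#' matching the rule that the LLM is consulted when all candidates fall
#' below the threshold. Grouping by CUI keeps, per concept, the single
#' best candidate row (highest similarity, then retrieval score).
#'
#' @param candidates a [search_index()] result.
#' @param mention the mention text compared against candidate labels.
#' @param theta_sim similarity threshold in \[0, 1\] (default 0.96).
#' @return a `mel_filtered` object with elements `all` (annotated
#'   candidates), `confident`, `by_cui`, `confident_by_cui`,
#'   `low_confidence` flag, `mention`, `theta_sim`.
#' @export
filter_candidates <- function(candidates, mention, theta_sim = 0.96) {
  if (!is.numeric(theta_sim) || length(theta_sim) != 1L ||
      is.na(theta_sim) || theta_sim < 0 || theta_sim > 1) {
    stop("theta_sim must be a single number in [0, 1]")
  }
  cand <- candidates
  if (nrow(cand)) {
    cand$similarity <- vapply(cand$label_norm, function(l)
      similarity(mention, l), 0)
  } else {
    cand$similarity <- numeric(0)
  }
  confident <- cand[cand$similarity >= theta_sim, , drop = FALSE]
  structure(list(
    all = cand,
    confident = confident,
    by_cui = group_best_by_cui(cand),
    confident_by_cui = group_best_by_cui(confident),
    low_confidence = nrow(cand) > 0 && nrow(confident) == 0,
    mention = mention,
    theta_sim = theta_sim
  ), class = "mel_filtered")
}

# One row per CUI: the candidate with the highest similarity, then
# retrieval score, then first label in lexicographic order.
group_best_by_cui <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(-cand$similarity, -cand$retrieval_score, cand$label_norm)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand$cui), , drop = FALSE]
  ord2 <- order(-cand$similarity, -cand$retrieval_score, cand$cui)
  cand <- cand[ord2, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Heuristic linking decision over filtered candidates
#'
#' Three scenarios: no candidates at all (`NO_CANDIDATE`); the confident
#' set maps to exactly one CUI (`DIRECT_LINK` — no LLM needed); otherwise
#' `AMBIGUOUS` — either several confident CUIs compete, or nothing reached
#' the threshold and the retrieved set is handed to the disambiguator as
#' low-confidence material.
#'
#' @param filtered a [filter_candidates()] result.
#' @return a `mel_decision`: list with `branch`
#'   (`"NO_CANDIDATE" | "DIRECT_LINK" | "AMBIGUOUS"`), `cui` (DIRECT_LINK
#'   only), `candidates` (AMBIGUOUS only: one row per CUI), and
#'   `low_confidence`.
#' @export
decide <- function(filtered) {
  stopifnot(inherits(filtered, "mel_filtered"))
  if (nrow(filtered$all) == 0L) {
    return(structure(list(branch = "NO_CANDIDATE", cui = NULL,
                          candidates = NULL, low_confidence = FALSE),
                     class = "mel_decision"))
  }
  conf <- filtered$confident_by_cui
  if (nrow(conf) == 1L) {
    return(structure(list(branch = "DIRECT_LINK", cui = conf$cui[1],
                          candidates = conf, low_confidence = FALSE),
                     class = "mel_decision"))
  }
  cand <- if (nrow(conf) >= 2L) conf else filtered$by_cui
  structure(list(branch = "AMBIGUOUS", cui = NULL, candidates = cand,
                 low_confidence = nrow(conf) == 0L),
            class = "mel_decision")
}
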
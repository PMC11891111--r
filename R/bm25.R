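#' Build a searchable BM25 index over a concept table
#'
#' Every (CUI, label) pair becomes one document with three searchable
#' fields: `label` (the pair's own label), `synonyms` (all other labels of
#' the same concept — the index "extends each term with its synonyms") and
#' `definition` (the concept's definitions, concatenated). Language,
#' semantic types and the label's linking score travel with the document.
#'
#' Scoring is Okapi BM25 with a lower-bound term (BM25+ style): for a
#' query token t occurring tf times in a document of field-length dl,
#' \deqn{w(t,d) = idf(t) \left( \frac{(k_1+1)\,tf}{k_1(1-b+b\,dl/avgdl)+tf}
#'   + \delta \right)}
#' with \eqn{idf(t) = \log(1 + (N-df+0.5)/(df+0.5))}; document frequencies
#' and average lengths are kept per field.
#'
#' @param concept_table a [aggregate_concepts()] result; must be non-empty.
#' @param k1,b,delta BM25 parameters (defaults 1.2, 0.75, 1.0).
#' @param definition_weight multiplier applied to the definition-field
#'   score in best-field queries (default 0.5 — definitions are context,
#'   not names).
#' @return a `vocab_index` object.
#' @export
build_index <- function(concept_table, k1 = 1.2, b = 0.75, delta = 1.0,
                        definition_weight = 0.5) {
  stopifnot(inherits(concept_table, "concept_table"))
  if (length(concept_table) == 0L) stop("cannot index an empty concept table")
  k1 <- as.numeric(k1); b <- as.numeric(b); delta <- as.numeric(delta)
  definition_weight <- as.numeric(definition_weight)

  rows <- list()
  for (entry in concept_table) {
    all_norms <- entry$labels$label_norm
    def_text <- paste(entry$definitions$definition, collapse = " ")
    for (i in seq_len(nrow(entry$labels))) {
      lr <- entry$labels[i, ]
      syn <- setdiff(unique(all_norms), lr$label_norm)
      rows[[length(rows) + 1L]] <- list(
        cui = entry$cui,
        label = lr$label,
        label_norm = lr$label_norm,
        lang = lr$lang,
        linking_score = lr$linking_score,
        sty = paste(entry$semantic_types, collapse = ";"),
        tok_label = tokenize_text(lr$label_norm)[[1]],
        tok_synonyms = if (length(syn)) tokenize_text(paste(syn, collapse = " "))[[1]] else character(),
        tok_definition = if (nzchar(def_text)) tokenize_text(def_text)[[1]] else character()
      )
    }
  }
  docs <- data.frame(
    doc_id = seq_along(rows),
    cui = vapply(rows, `[[`, "", "cui"),
    label = vapply(rows, `[[`, "", "label"),
    label_norm = vapply(rows, `[[`, "", "label_norm"),
    lang = vapply(rows, `[[`, "", "lang"),
    linking_score = vapply(rows, function(r) as.integer(r$linking_score), 0L),
    sty = vapply(rows, `[[`, "", "sty"),
    stringsAsFactors = FALSE
  )
  docs$tok_label <- lapply(rows, `[[`, "tok_label")
  docs$tok_synonyms <- lapply(rows, `[[`, "tok_synonyms")
  docs$tok_definition <- lapply(rows, `[[`, "tok_definition")

  field_stats <- lapply(c(label = "tok_label", synonyms = "tok_synonyms",
                          definition = "tok_definition"), function(col) {
    toks <- docs[[col]]
    lens <- vapply(toks, length, 0L)
    dfreq <- table(unlist(lapply(toks, unique)))
    list(df = stats::setNames(as.integer(dfreq), names(dfreq)),
         avgdl = if (any(lens > 0)) mean(lens) else 0,
         lens = lens)
  })

  label_to_cuis <- lapply(split(docs$cui, docs$label_norm), function(v)
    sort(unique(v)))

  idx <- structure(list(
    docs = docs,
    field_stats = field_stats,
    params = list(k1 = k1, b = b, delta = delta,
                  definition_weight = definition_weight),
    analyzer = list(normalize = "nfc+lower+latin-ascii",
                    token_split = "non-alphanumeric"),
    concepts = concept_table,
    label_to_cuis = label_to_cuis
  ), class = "vocab_index")
  idx$build_hash <- index_hash(idx)
  idx
}

index_hash <- function(index) {
  payload <- paste(
    stable_serialize(index$params),
    stable_serialize(index$analyzer),
    paste(index$docs$cui, index$docs$label_norm, index$docs$lang,
          index$docs$linking_score, collapse = ";"),
    sep = "#"
  )
  fnv1a(payload)
}

#' @export
print.vocab_index <- function(x, ...) {
  cat(sprintf("<vocab_index> %d documents over %d concepts (hash %s)\n",
              nrow(x$docs), length(x$concepts), x$build_hash))
  cat(sprintf("  BM25 k1=%g b=%g delta=%g\n",
              x$params$k1, x$params$b, x$params$delta))
  invisible(x)
}

# BM25+ weight of one term with term frequency tf in a doc of length dl.
bm25_weight <- function(tf, df, n_docs, dl, avgdl, k1, b, delta) {
  if (tf <= 0 || df <= 0) return(0)
  idf <- log(1 + (n_docs - df + 0.5) / (df + 0.5))
  norm <- if (avgdl > 0) k1 * (1 - b + b * dl / avgdl) else k1
  idf * ((k1 + 1) * tf / (norm + tf) + delta)
}

# Allowed Levenshtein edit budget for a query token under fuzzy matching.
fuzzy_budget <- function(token) ifelse(nchar(token) <= 5L, 1L, 2L)

# Which of `doc_tokens` are within the fuzzy budget of query token `t`?
fuzzy_hits <- function(t, doc_tokens) {
  if (length(doc_tokens) == 0L) return(logical(0))
  exact <- doc_tokens == t
  if (all(exact)) return(exact)
  d <- utils::adist(t, doc_tokens)[1, ]
  d <= fuzzy_budget(t)
}

#' Serialize a vocabulary index to a directory
#'
#' Writes a plain-text artifact: `manifest.json` (analyzer config, BM25
#' parameters, build hash, format version) plus `docs.jsonl` and
#' `concepts.jsonl`. [load_index()] rebuilds the collection statistics from
#' the documents, so a round trip reproduces scores bit-identically.
#'
#' @param index a `vocab_index`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir) {
  stopifnot(inherits(index, "vocab_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format_version = 1L, build_hash = index$build_hash,
                   params = index$params, analyzer = index$analyzer)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  doc_recs <- lapply(seq_len(nrow(index$docs)), function(i) {
    d <- index$docs[i, ]
    list(doc_id = d$doc_id, cui = d$cui, label = d$label,
         label_norm = d$label_norm, lang = d$lang,
         linking_score = d$linking_score, sty = d$sty,
         tok_label = I(d$tok_label[[1]]),
         tok_synonyms = I(d$tok_synonyms[[1]]),
         tok_definition = I(d$tok_definition[[1]]))
  })
  write_jsonl(doc_recs, file.path(dir, "docs.jsonl"))
  con_recs <- lapply(index$concepts, function(e) {
    list(cui = e$cui,
         labels = e$labels,
         semantic_types = I(e$semantic_types),
         synonyms = I(e$synonyms),
         definitions = e$definitions)
  })
  write_jsonl(con_recs, file.path(dir, "concepts.jsonl"))
  invisible(dir)
}

#' Load a vocabulary index from a directory written by [save_index()]
#' @param dir index directory.
#' @return a `vocab_index`.
#' @export
load_index <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("not an index directory: ", dir)
  manifest <- jsonlite::fromJSON(mf_path)
  if (!identical(as.integer(manifest$format_version), 1L)) {
    stop("unsupported index format version: ", manifest$format_version)
  }
  con_recs <- read_jsonl(file.path(dir, "concepts.jsonl"))
  entries <- lapply(con_recs, function(r) {
    labs <- as.data.frame(r$labels, stringsAsFactors = FALSE)
    labs$linking_score <- as.integer(labs$linking_score)
    defs <- if (length(r$definitions)) {
      as.data.frame(r$definitions, stringsAsFactors = FALSE)
    } else {
      data.frame(definition = character(), def_source = character(),
                 stringsAsFactors = FALSE)
    }
    list(cui = r$cui, labels = labs,
         semantic_types = as.character(unlist(r$semantic_types)),
         synonyms = as.character(unlist(r$synonyms)), definitions = defs)
  })
  names(entries) <- vapply(entries, `[[`, "", "cui")
  tab <- structure(entries[order(names(entries))], class = "concept_table")
  idx <- build_index(tab,
                     k1 = manifest$params$k1, b = manifest$params$b,
                     delta = manifest$params$delta,
                     definition_weight = manifest$params$definition_weight)
  if (!identical(idx$build_hash, manifest$build_hash)) {
    stop("index build hash mismatch: artifact was written by a different build")
  }
  idx
}
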
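# Independent reference implementations used as oracles. These deliberately
# recompute everything by brute force, sharing no code with the package
# internals they check.

# --- Ratcliff-Obershelp similarity, quadratic-time reference ---------------
# Finds all common substrings via an equality matrix, picks the maximal one
# (ties: smallest start in a, then in b), recurses on both sides.
ref_similarity <- function(a, b) {
  a <- cuilink::normalize_text(a)
  b <- cuilink::normalize_text(b)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) == 0 && length(cb) == 0) return(1)
  if (length(ca) == 0 || length(cb) == 0) return(0)
  matched <- function(x, y) {
    nx <- length(x); ny <- length(y)
    if (nx == 0 || ny == 0) return(0)
    eq <- outer(x, y, "==")
    run <- matrix(0L, nx, ny)
    best <- c(size = 0L, ai = 0L, bi = 0L)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (eq[i, j]) {
        run[i, j] <- if (i > 1 && j > 1) run[i - 1, j - 1] + 1L else 1L
      }
    }
    mx <- max(run)
    if (mx == 0L) return(0)
    hits <- which(run == mx, arr.ind = TRUE)
    starts <- cbind(hits[, 1] - mx + 1L, hits[, 2] - mx + 1L)
    ord <- order(starts[, 1], starts[, 2])
    ai <- starts[ord[1], 1]; bi <- starts[ord[1], 2]
    mx +
      matched(x[seq_len(ai - 1L)], y[seq_len(bi - 1L)]) +
      matched(if (ai + mx <= nx) x[(ai + mx):nx] else character(),
              if (bi + mx <= ny) y[(bi + mx):ny] else character())
  }
  2 * matched(ca, cb) / (length(ca) + length(cb))
}

# --- Brute-force retrieval oracle ------------------------------------------
# Re-derives the document collection from the concept table and scores every
# document directly with the documented formulas.
ref_docs <- function(concept_table) {
  rows <- list()
  for (e in concept_table) {
    norms <- e$labels$label_norm
    def_toks <- unlist(cuilink::tokenize_text(
      paste(e$definitions$definition, collapse = " ")))
    for (i in seq_len(nrow(e$labels))) {
      lr <- e$labels[i, ]
      rows[[length(rows) + 1]] <- list(
        cui = e$cui, label_norm = lr$label_norm, lang = lr$lang,
        linking_score = lr$linking_score,
        tok = list(
          label = unlist(cuilink::tokenize_text(lr$label_norm)),
          synonyms = unlist(cuilink::tokenize_text(
            paste(setdiff(unique(norms), lr$label_norm), collapse = " "))),
          definition = def_toks))
    }
  }
  rows
}

ref_bm25_term <- function(tf, df, n, dl, avgdl, k1, b, delta) {
  if (tf <= 0 || df <= 0) return(0)
  log(1 + (n - df + 0.5) / (df + 0.5)) *
    ((k1 + 1) * tf / (k1 * (1 - b + b * dl / avgdl) + tf) + delta)
}

ref_budget <- function(tok) if (nchar(tok) <= 5) 1L else 2L

ref_tf <- function(tok, doc_toks, fuzzy) {
  if (length(doc_toks) == 0) return(0L)
  if (!fuzzy) return(sum(doc_toks == tok))
  sum(utils::adist(tok, doc_toks)[1, ] <= ref_budget(tok))
}

# exhaustive scoring for one query under one q_type; returns the candidate
# table sorted like search_index()
ref_search <- function(concept_table, text, q_type, k = 1000L,
                       params = list(k1 = 1.2, b = 0.75, delta = 1.0,
                                     definition_weight = 0.5),
                       boost_words = cuilink::default_boost_words(),
                       boost_factor = 2.0, lang = "any") {
  docs <- ref_docs(concept_table)
  n <- length(docs)
  qn <- cuilink::normalize_text(text)
  qtok <- unique(unlist(cuilink::tokenize_text(qn)))
  lang_want <- switch(q_type, Multi_match_SPA = "SPA",
                      Multi_match = "any", Multi_match_boosted = "any",
                      lang)
  field_len <- function(f) vapply(docs, function(d) length(d$tok[[f]]), 0L)
  avgdl <- lapply(c(label = "label", synonyms = "synonyms",
                    definition = "definition"), function(f) {
    l <- field_len(f); if (any(l > 0)) mean(l) else 0
  })
  dfreq <- function(tok, f, fuzzy) {
    sum(vapply(docs, function(d) ref_tf(tok, d$tok[[f]], fuzzy) > 0, TRUE))
  }

  score <- numeric(n); hit <- logical(n)
  for (di in seq_len(n)) {
    d <- docs[[di]]
    if (lang_want != "any" && d$lang != lang_want) next
    if (q_type == "Exact") {
      if (d$label_norm != qn) next
      hit[di] <- TRUE
      s <- 0
      for (t in qtok) {
        s <- s + ref_bm25_term(ref_tf(t, d$tok$label, FALSE),
                               dfreq(t, "label", FALSE), n,
                               length(d$tok$label), avgdl$label,
                               params$k1, params$b, params$delta)
      }
      score[di] <- s
    } else if (q_type == "Basic_Fuzzy") {
      tfs <- vapply(qtok, function(t) ref_tf(t, d$tok$label, TRUE), 0L)
      if (length(qtok) == 0 || any(tfs == 0)) next
      hit[di] <- TRUE
      s <- 0
      for (qi in seq_along(qtok)) {
        s <- s + ref_bm25_term(tfs[qi], dfreq(qtok[qi], "label", TRUE), n,
                               length(d$tok$label), avgdl$label,
                               params$k1, params$b, params$delta)
      }
      score[di] <- s
    } else {
      fs <- c(label = 0, synonyms = 0, definition = 0)
      any_m <- FALSE
      for (f in names(fs)) {
        for (t in qtok) {
          tf <- ref_tf(t, d$tok[[f]], TRUE)
          if (tf > 0) any_m <- TRUE
          fs[f] <- fs[f] + ref_bm25_term(tf, dfreq(t, f, TRUE), n,
                                         length(d$tok[[f]]), avgdl[[f]],
                                         params$k1, params$b, params$delta)
        }
      }
      if (!any_m) next
      hit[di] <- TRUE
      fs["definition"] <- fs["definition"] * params$definition_weight
      s <- max(fs)
      if (q_type == "Multi_match_boosted" &&
          any(d$tok$label %in% cuilink::normalize_text(boost_words))) {
        s <- s * boost_factor
      }
      score[di] <- s
    }
  }
  res <- data.frame(
    cui = vapply(docs, `[[`, "", "cui")[hit],
    label_norm = vapply(docs, `[[`, "", "label_norm")[hit],
    linking_score = vapply(docs, function(d) as.integer(d$linking_score),
                           0L)[hit],
    retrieval_score = score[hit], stringsAsFactors = FALSE)
  res <- res[order(-res$retrieval_score, -res$linking_score, res$cui,
                   res$label_norm), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, k)
}

# --- Small fixtures --------------------------------------------------------
simple_vocab_df <- function(rows) {
  cols <- c("cui", "label", "lang", "source", "tty", "sty",
            "definition", "def_source")
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(lapply(setNames(cols, cols), function(cn)
      as.character(r[[cn]] %||% NA)), stringsAsFactors = FALSE)
  }))
  attr(df, "definitions") <- data.frame(
    cui = character(), definition = character(), def_source = character(),
    stringsAsFactors = FALSE)
  class(df) <- c("term_records", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixture vocabulary used across MEL tests: includes the carcinoma concept
# and a homonym surface under two CUIs
fixture_concepts <- function() {
  aggregate_concepts(simple_vocab_df(list(
    list(cui = "C0007097", label = "carcinoma", lang = "SPA", source = "MSH",
         sty = "Neoplastic Process",
         definition = "A malignant epithelial neoplasm.", def_source = "NCI"),
    list(cui = "C0007097", label = "carcinoma", lang = "ENG",
         source = "NCI", sty = "Neoplastic Process"),
    list(cui = "C0006141", label = "mama derecha", lang = "SPA",
         source = "SNOMEDCT_US", sty = "Body Part, Organ, or Organ Component",
         definition = "The right breast.", def_source = "MSH"),
    list(cui = "C0006141", label = "right breast", lang = "ENG",
         source = "SNOMEDCT_US"),
    list(cui = "C0183683", label = "boost", lang = "ENG", source = "NCI",
         sty = "Therapeutic or Preventive Procedure",
         definition = "An additional dose of radiation.", def_source = "NCI"),
    list(cui = "C1282911", label = "boost", lang = "ENG", source = "MSH",
         sty = "Pharmacologic Substance",
         definition = "A nutritional supplement product.", def_source = "MSH"),
    list(cui = "C0024881", label = "mastectomía", lang = "SPA",
         source = "MDR", sty = "Therapeutic or Preventive Procedure"),
    list(cui = "C0030926", label = "quimioterapia", lang = "SPA",
         source = "MSH", sty = "Therapeutic or Preventive Procedure",
         definition = "Drug treatment of cancer.", def_source = "NCI")
  )))
}

apply_typo_for_test <- function(s) {
  toks <- strsplit(s, " ")[[1]]
  i <- which.max(nchar(toks))
  w <- toks[i]
  if (nchar(w) < 3) return(s)
  p <- sample(seq_len(nchar(w)), 1)
  substr(w, p, p) <- "x"
  toks[i] <- w
  paste(toks, collapse = " ")
}
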
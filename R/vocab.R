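#' Parse UMLS Rich Release Format (RRF) vocabulary files
#'
#' Reads `MRCONSO.RRF` (atoms), `MRSTY.RRF` (semantic types) and
#' `MRDEF.RRF` (definitions) and produces one term record per retained
#' MRCONSO atom, joined with its concept's semantic types. Definitions are
#' attached per CUI (a concept usually has several, from different source
#' vocabularies) and carried on the `"definitions"` attribute of the result.
#'
#' RRF files are pipe-delimited with no header; a trailing pipe is
#' tolerated. The columns used are MRCONSO: CUI (1), LAT (2), SAB (12),
#' TTY (13), SUPPRESS (17), STR (15); MRSTY: CUI (1), STY (4); MRDEF:
#' CUI (1), SAB (5), DEF (6) — 1-based positions per the UMLS column order.
#'
#' @param mrconso_path path to MRCONSO.RRF.
#' @param mrsty_path path to MRSTY.RRF, or `NULL` to skip semantic types.
#' @param mrdef_path path to MRDEF.RRF, or `NULL` to skip definitions.
#' @param lang_filter character vector of language codes (LAT) to keep,
#'   e.g. `c("SPA", "ENG")`; `NULL` keeps every language.
#' @param keep_suppressed keep atoms with SUPPRESS != "N"? Default drops
#'   them, following UMLS convention.
#' @return a `term_records` data frame with columns
#'   `cui, label, lang, source, tty, sty, definition, def_source` and a
#'   `"definitions"` attribute (data frame `cui, definition, def_source`).
#'   Rows with the wrong column count are skipped with a warning; the skip
#'   count is on the `"skipped"` attribute.
#' @export
parse_rrf <- function(mrconso_path, mrsty_path = NULL, mrdef_path = NULL,
                      lang_filter = c("SPA", "ENG"), keep_suppressed = FALSE) {
  rows <- read_rrf_rows(mrconso_path, min_cols = 17)
  if (length(rows$fields) == 0L) {
    stop("unusable vocabulary: no parseable rows in ", mrconso_path)
  }
  f <- rows$fields
  atoms <- data.frame(
    cui = vapply(f, `[`, "", 1L),
    lang = vapply(f, `[`, "", 2L),
    source = vapply(f, `[`, "", 12L),
    tty = vapply(f, `[`, "", 13L),
    label = vapply(f, `[`, "", 15L),
    suppress = vapply(f, `[`, "", 17L),
    stringsAsFactors = FALSE
  )
  if (!keep_suppressed) atoms <- atoms[atoms$suppress == "N", , drop = FALSE]
  if (!is.null(lang_filter)) {
    atoms <- atoms[atoms$lang %in% lang_filter, , drop = FALSE]
  }
  atoms <- atoms[nzchar(normalize_text(atoms$label)), , drop = FALSE]

  sty_map <- list()
  if (!is.null(mrsty_path)) {
    srows <- read_rrf_rows(mrsty_path, min_cols = 4)$fields
    if (length(srows)) {
      sty_df <- data.frame(
        cui = vapply(srows, `[`, "", 1L),
        sty = vapply(srows, `[`, "", 4L),
        stringsAsFactors = FALSE
      )
      sty_map <- lapply(split(sty_df$sty, sty_df$cui), function(v) sort(unique(v)))
    }
  }

  defs <- data.frame(cui = character(), definition = character(),
                     def_source = character(), stringsAsFactors = FALSE)
  if (!is.null(mrdef_path)) {
    drows <- read_rrf_rows(mrdef_path, min_cols = 6)$fields
    if (length(drows)) {
      defs <- data.frame(
        cui = vapply(drows, `[`, "", 1L),
        definition = vapply(drows, `[`, "", 6L),
        def_source = vapply(drows, `[`, "", 5L),
        stringsAsFactors = FALSE
      )
    }
  }

  recs <- data.frame(
    cui = atoms$cui, label = atoms$label, lang = atoms$lang,
    source = atoms$source, tty = atoms$tty,
    sty = vapply(atoms$cui, function(cc)
      paste(sty_map[[cc]] %||% character(), collapse = ";"), ""),
    definition = NA_character_, def_source = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(recs) <- NULL
  attr(recs, "definitions") <- defs
  attr(recs, "skipped") <- rows$skipped +
    (if (!is.null(mrsty_path)) read_rrf_rows(mrsty_path, 4)$skipped else 0L) +
    (if (!is.null(mrdef_path)) read_rrf_rows(mrdef_path, 6)$skipped else 0L)
  class(recs) <- c("term_records", "data.frame")
  recs
}

# Split pipe-delimited rows; count (and warn about) malformed ones.
read_rrf_rows <- function(path, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "|", fixed = TRUE)
  ok <- vapply(fields, length, 0L) >= min_cols
  skipped <- sum(!ok)
  if (skipped > 0L) {
    warning(sprintf("%d malformed row(s) skipped in %s", skipped, path))
  }
  list(fields = fields[ok], skipped = skipped)
}

#' Load a simplified (JSON-lines or TSV) vocabulary fixture
#'
#' A licensing-free alternative to RRF with the same semantics: one term
#' record per line with fields `cui, label, lang, source, sty, definition,
#' def_source` (`sty`, `definition`, `def_source` optional). JSON-lines is
#' detected by a leading `{`; anything else is read as tab-separated with a
#' header row.
#'
#' @param path input file.
#' @return a `term_records` data frame (see [parse_rrf()]); an empty file
#'   yields zero records, not an error. Records missing `cui` or `label`
#'   are rejected with a warning.
#' @export
load_simple_vocab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- c("cui", "label", "lang", "source", "tty", "sty",
            "definition", "def_source")
  if (length(lines) == 0L) {
    recs <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                          stringsAsFactors = FALSE)
  } else if (startsWith(trimws(lines[1]), "{")) {
    parsed <- lapply(lines, function(l) jsonlite::fromJSON(l))
    recs <- do.call(rbind, lapply(parsed, function(p) {
      as.data.frame(lapply(setNames(cols, cols), function(cn)
        as.character(p[[cn]] %||% NA_character_)), stringsAsFactors = FALSE)
    }))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", quote = "")
    for (cn in setdiff(cols, names(tab))) tab[[cn]] <- NA_character_
    recs <- tab[, cols]
  }
  bad <- is.na(recs$cui) | !nzchar(recs$cui) |
    is.na(recs$label) | !nzchar(normalize_text(recs$label))
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected: missing cui or empty label")
    recs <- recs[!bad, , drop = FALSE]
  }
  recs$lang[is.na(recs$lang) | !nzchar(recs$lang)] <- "other"
  rownames(recs) <- NULL
  attr(recs, "definitions") <-
    data.frame(cui = character(), definition = character(),
               def_source = character(), stringsAsFactors = FALSE)
  class(recs) <- c("term_records", "data.frame")
  recs
}

#' Aggregate term records into a concept table
#'
#' Groups records per CUI. Within a concept, labels are grouped by their
#' normalized form; the *linking score* of a normalized label is the number
#' of source records carrying it — the same label asserted by three source
#' vocabularies scores 3. Labels are ranked by descending linking score,
#' ties broken by normalized label. Synonyms are the union of all the
#' concept's raw labels; all definitions are retained with their source
#' codes (selection between them happens at disambiguation time).
#'
#' Homonymy is preserved: the same surface under two CUIs stays in both
#' entries — no merging across concepts ever happens here.
#'
#' @param records a `term_records` data frame.
#' @return a `concept_table`: named list (by CUI) of concept entries, each
#'   with `cui`, `labels` (data frame `label, label_norm, lang,
#'   linking_score`, ranked), `semantic_types`, `synonyms`, `definitions`
#'   (data frame `definition, def_source`).
#' @export
aggregate_concepts <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    tab <- structure(list(), class = "concept_table")
    return(tab)
  }
  records$label_norm <- normalize_text(records$label)
  ext_defs <- attr(records, "definitions") %||%
    data.frame(cui = character(), definition = character(),
               def_source = character(), stringsAsFactors = FALSE)

  entries <- lapply(split(records, records$cui), function(g) {
    cui <- g$cui[1]
    # linking score per normalized label, counted over source records
    score <- table(g$label_norm)
    # one label row per (normalized label, language); the row inherits the
    # linking score of its normalized-label group
    key <- paste(g$label_norm, g$lang, sep = "\r")
    first <- !duplicated(key)
    lab <- data.frame(
      label_norm = g$label_norm[first],
      lang = g$lang[first],
      stringsAsFactors = FALSE
    )
    # representative raw label: lexicographically smallest variant, so the
    # table is invariant under input shuffling
    lab$label <- vapply(seq_len(nrow(lab)), function(i) {
      v <- g$label[g$label_norm == lab$label_norm[i] & g$lang == lab$lang[i]]
      min(v)
    }, "")
    lab$linking_score <- as.integer(score[lab$label_norm])
    ord <- order(-lab$linking_score, lab$label_norm, lab$lang)
    lab <- lab[ord, c("label", "label_norm", "lang", "linking_score")]
    rownames(lab) <- NULL

    sty <- sort(unique(unlist(strsplit(g$sty[!is.na(g$sty)], ";", fixed = TRUE))))
    sty <- sty[nzchar(sty)]

    dd <- g[!is.na(g$definition) & nzchar(g$definition),
            c("definition", "def_source"), drop = FALSE]
    de <- ext_defs[ext_defs$cui == cui, c("definition", "def_source"),
                   drop = FALSE]
    defs <- rbind(dd, de)
    defs$def_source[is.na(defs$def_source)] <- ""
    defs <- defs[!duplicated(paste(defs$definition, defs$def_source)), ,
                 drop = FALSE]
    defs <- defs[order(defs$def_source, defs$definition), , drop = FALSE]
    rownames(defs) <- NULL

    list(cui = cui, labels = lab, semantic_types = sty,
         synonyms = sort(unique(g$label)), definitions = defs)
  })
  entries <- entries[order(names(entries))]
  structure(entries, class = "concept_table")
}

#' @export
print.concept_table <- function(x, ...) {
  n_lab <- sum(vapply(x, function(e) nrow(e$labels), 0L))
  cat(sprintf("<concept_table> %d concepts, %d (CUI, label) pairs\n",
              length(x), n_lab))
  invisible(x)
}
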
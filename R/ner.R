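#' Construct a clinical note
#' @param text note text (Spanish by default); must be non-empty after
#'   whitespace stripping.
#' @param note_id identifier string.
#' @return a `clinical_note` list.
#' @export
clinical_note <- function(text, note_id = "note-1") {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("note text must be a non-empty string")
  }
  structure(list(note_id = as.character(note_id), text = text),
            class = "clinical_note")
}

#' Default Spanish oncology acronym dictionary
#'
#' Shipped stand-in dictionary mapping common short forms to their full
#' descriptions (e.g. "ca." to "cáncer"); fully configurable — pass your
#' own named list to [preprocess()].
#' @return named character vector (short form -> expansion).
#' @export
default_acronyms <- function() {
  path <- system.file("extdata", "acronyms.json", package = "cuilink")
  if (nzchar(path)) {
    unlist(jsonlite::fromJSON(path))
  } else {
    c("ca." = "cáncer", "qt" = "quimioterapia", "rt" = "radioterapia",
      "mtx" = "metotrexato", "dx" = "diagnóstico", "tto" = "tratamiento")
  }
}

#' Preprocess a clinical note
#'
#' Expands acronyms to their full descriptions (regular-expression match on
#' word boundaries, case-insensitive), splits the expanded text into
#' sentences and tokenizes each sentence, keeping an offset map that
#' relates every expanded-text position back to the original note so that
#' entity spans can be reported on the raw text.
#'
#' @param note a [clinical_note()] (or a plain string).
#' @param acronym_dict named character vector mapping short forms to
#'   expansions; [default_acronyms()] by default.
#' @return a `preprocessed_note`: list with `note`, `expanded_text`,
#'   `tokens` (data frame `token, start, end, sentence` — 1-based
#'   inclusive offsets into the expanded text) and `segments` (the offset
#'   map).
#' @export
preprocess <- function(note, acronym_dict = default_acronyms()) {
  if (is.character(note)) note <- clinical_note(note)
  stopifnot(inherits(note, "clinical_note"))
  exp <- expand_acronyms(note$text, acronym_dict)
  tokens <- tokenize_with_offsets(exp$text)
  structure(list(note = note, expanded_text = exp$text, tokens = tokens,
                 segments = exp$segments),
            class = "preprocessed_note")
}

# Replace acronym occurrences; returns expanded text plus a segment table
# (orig_start/orig_end/exp_start/exp_end/changed, 1-based inclusive).
expand_acronyms <- function(text, acronym_dict) {
  if (length(acronym_dict) == 0L) {
    seg <- data.frame(orig_start = 1L, orig_end = nchar(text),
                      exp_start = 1L, exp_end = nchar(text),
                      changed = FALSE)
    return(list(text = text, segments = seg))
  }
  # longest short forms first so e.g. "ca." wins over "ca"
  dict <- acronym_dict[order(-nchar(names(acronym_dict)))]
  pats <- vapply(names(dict), function(a)
    paste0("(?<![\\p{L}\\p{N}])", stringi::stri_replace_all_regex(
      a, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"), "(?![\\p{L}\\p{N}])"), "")
  hits <- do.call(rbind, lapply(seq_along(pats), function(i) {
    loc <- stringi::stri_locate_all_regex(
      text, pats[i], case_insensitive = TRUE)[[1]]
    if (all(is.na(loc[, 1]))) return(NULL)
    data.frame(start = loc[, 1], end = loc[, 2],
               repl = unname(dict[i]), stringsAsFactors = FALSE)
  }))
  if (is.null(hits) || nrow(hits) == 0L) {
    seg <- data.frame(orig_start = 1L, orig_end = nchar(text),
                      exp_start = 1L, exp_end = nchar(text),
                      changed = FALSE)
    return(list(text = text, segments = seg))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  hits <- hits[!duplicated(hits$start), , drop = FALSE]
  # drop overlaps (earlier, longer short forms win)
  keep <- rep(TRUE, nrow(hits)); last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] <= last_end) keep[i] <- FALSE
    else last_end <- hits$end[i]
  }
  hits <- hits[keep, , drop = FALSE]

  out <- character(0); segs <- list(); pos <- 1L; epos <- 1L
  add_seg <- function(os, oe, es, ee, ch) {
    segs[[length(segs) + 1L]] <<- data.frame(
      orig_start = os, orig_end = oe, exp_start = es, exp_end = ee,
      changed = ch)
  }
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > pos) {
      chunk <- substr(text, pos, hits$start[i] - 1L)
      out <- c(out, chunk)
      add_seg(pos, hits$start[i] - 1L, epos, epos + nchar(chunk) - 1L, FALSE)
      epos <- epos + nchar(chunk)
    }
    out <- c(out, hits$repl[i])
    add_seg(hits$start[i], hits$end[i], epos,
            epos + nchar(hits$repl[i]) - 1L, TRUE)
    epos <- epos + nchar(hits$repl[i])
    pos <- hits$end[i] + 1L
  }
  if (pos <= nchar(text)) {
    chunk <- substr(text, pos, nchar(text))
    out <- c(out, chunk)
    add_seg(pos, nchar(text), epos, epos + nchar(chunk) - 1L, FALSE)
  }
  list(text = paste(out, collapse = ""), segments = do.call(rbind, segs))
}

# Map a 1-based inclusive span on the expanded text back to the original.
map_span_to_original <- function(segments, start, end) {
  map_pos <- function(pos, is_end) {
    i <- which(segments$exp_start <= pos & segments$exp_end >= pos)[1]
    if (is.na(i)) return(if (is_end) max(segments$orig_end) else 1L)
    if (segments$changed[i]) {
      if (is_end) segments$orig_end[i] else segments$orig_start[i]
    } else {
      segments$orig_start[i] + (pos - segments$exp_start[i])
    }
  }
  c(map_pos(start, FALSE), map_pos(end, TRUE))
}

# Tokenize with offsets and sentence indices (0-based sentences).
tokenize_with_offsets <- function(text) {
  loc <- stringi::stri_locate_all_regex(text, "[\\p{L}\\p{N}]+")[[1]]
  if (all(is.na(loc[, 1]))) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), sentence = integer()))
  }
  # sentence boundaries: terminal punctuation followed by space, or newline
  bnd <- stringi::stri_locate_all_regex(text, "[.!?]+\\s+|\\n+")[[1]]
  bstarts <- if (all(is.na(bnd[, 1]))) integer(0) else bnd[, 2]
  sent <- vapply(loc[, 1], function(s) sum(bstarts < s), 0L)
  data.frame(
    token = stringi::stri_sub(text, loc[, 1], loc[, 2]),
    start = as.integer(loc[, 1]), end = as.integer(loc[, 2]),
    sentence = as.integer(sent), stringsAsFactors = FALSE)
}

#' Build a gazetteer recognizer
#'
#' A deterministic reference recognizer: matches lexicon surfaces against
#' the token stream, case- and accent-insensitively, longest match first,
#' left to right, never across sentence boundaries, and emits BIO tags.
#' It exists so the full pipeline is testable without a trained NER model;
#' a transformer-based recognizer can be plugged in behind the same
#' interface (a function from the token table to a BIO tag vector).
#'
#' @param lexicon named character vector: surface -> context label.
#' @return a recognizer function `(tokens) -> character` of BIO tags.
#' @export
gazetteer_recognizer <- function(lexicon) {
  stopifnot(length(lexicon) > 0L, all(nzchar(names(lexicon))))
  entries <- data.frame(label = unname(lexicon), stringsAsFactors = FALSE)
  toks <- tokenize_text(names(lexicon))
  entries$ntok <- vapply(toks, length, 0L)
  entries$key <- vapply(toks, paste, "", collapse = " ")
  entries <- entries[entries$ntok > 0L, , drop = FALSE]
  # longest first, then leftmost entry key for determinism
  entries <- entries[order(-entries$ntok, entries$key), , drop = FALSE]

  function(tokens) {
    tags <- rep("O", nrow(tokens))
    if (nrow(tokens) == 0L) return(tags)
    norm <- normalize_text(tokens$token)
    i <- 1L
    while (i <= nrow(tokens)) {
      matched <- FALSE
      for (e in seq_len(nrow(entries))) {
        n <- entries$ntok[e]
        j <- i + n - 1L
        if (j > nrow(tokens)) next
        if (tokens$sentence[j] != tokens$sentence[i]) next
        if (paste(norm[i:j], collapse = " ") == entries$key[e]) {
          tags[i] <- paste0("B-", entries$label[e])
          if (n > 1L) tags[(i + 1L):j] <- paste0("I-", entries$label[e])
          i <- j + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
    tags
  }
}

#' Recognize medical entities in a note
#'
#' Preprocesses the note, runs the recognizer over the token stream and
#' merges contiguous same-label BIO runs into entities. Spans are 0-based,
#' half-open, on the *original* (pre-expansion) text; `surface` is the
#' original slice and `surface_expanded` the acronym-expanded form that
#' downstream linking should use.
#'
#' @param note a [clinical_note()] or string.
#' @param recognizer a recognizer function (see [gazetteer_recognizer()]).
#' @param acronym_dict passed to [preprocess()].
#' @return data frame of entities: `note_id, surface, surface_expanded,
#'   label, start, end, sentence_index`, ordered by span start.
#' @export
recognize <- function(note, recognizer, acronym_dict = default_acronyms()) {
  if (is.character(note)) note <- clinical_note(note)
  prep <- preprocess(note, acronym_dict)
  tags <- tryCatch(recognizer(prep$tokens), error = function(e)
    stop("recognizer failed on note ", note$note_id, ": ",
         conditionMessage(e)))
  stopifnot(length(tags) == nrow(prep$tokens))
  ents <- list()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      label <- substring(tags[i], 3L)
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == paste0("I-", label)) {
        j <- j + 1L
      }
      es <- prep$tokens$start[i]; ee <- prep$tokens$end[j]
      orig <- map_span_to_original(prep$segments, es, ee)
      ents[[length(ents) + 1L]] <- data.frame(
        note_id = note$note_id,
        surface = substr(note$text, orig[1], orig[2]),
        surface_expanded = substr(prep$expanded_text, es, ee),
        label = label,
        start = orig[1] - 1L, end = orig[2],
        sentence_index = prep$tokens$sentence[i],
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(ents) == 0L) {
    return(data.frame(note_id = character(), surface = character(),
                      surface_expanded = character(), label = character(),
                      start = integer(), end = integer(),
                      sentence_index = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ents)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
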
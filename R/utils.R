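#' Normalize a surface string for matching
#'
#' Matching in the background knowledge base is done on a canonical form:
#' NFC unicode normalization, lowercasing, accent folding (so Spanish and
#' English variants such as "cáncer"/"cancer" compare equal) and whitespace
#' collapse. Raw strings are always preserved alongside for display.
#'
#' @param x character vector.
#' @return character vector of normalized strings.
#' @export
#' @examples
#' normalize_text("  Cáncer  de  MAMA ")
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Tokenize a normalized string
#'
#' Splits on any run of non-alphanumeric characters; empty tokens dropped.
#' @param x character vector (normalized or raw; normalization applied first).
#' @return list of character vectors, one per input element.
#' @export
tokenize_text <- function(x) {
  x <- normalize_text(x)
  toks <- stringi::stri_split_regex(x, "[^\\p{L}\\p{N}]+", omit_empty = TRUE)
  lapply(toks, as.character)
}

# FNV-1a 32-bit hash over a string; used for cache keys and the index build
# hash. Returned as 8 hex digits. Arithmetic kept in double precision (exact
# below 2^53), reduced mod 2^32 at each step.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of two doubles representing 32-bit unsigned ints
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}

# Stable serialization of a (possibly nested) list of atomic values for
# hashing: names sorted, scalars formatted with full precision.
stable_serialize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- as.character(seq_along(x))
    ord <- order(nm)
    inner <- vapply(ord, function(i) {
      paste0(nm[i], "=", stable_serialize(x[[i]]))
    }, character(1))
    paste0("{", paste(inner, collapse = ","), "}")
  } else if (is.numeric(x)) {
    paste(format(x, digits = 17, scientific = TRUE), collapse = "|")
  } else {
    paste(as.character(x), collapse = "|")
  }
}

#' Read a JSON-lines file
#' @param path file path.
#' @return list of parsed records (each a named list).
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Write records as JSON-lines
#' @param records list of named lists.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null",
                                digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
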
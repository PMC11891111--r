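#' Ratcliff-Obershelp string similarity
#'
#' The candidate filter compares a mention with a retrieved label using the
#' Ratcliff-Obershelp matching ratio \eqn{s(a,b) = 2M/(|a|+|b|)}, where M
#' is the total length of the matching blocks found by recursively taking
#' the longest common substring and matching the pieces to its left and
#' right. Strings are normalized (lowercase, accent-folded, whitespace
#' collapsed) before comparison, so "Cáncer" and "cancer" are identical.
#'
#' `s(a, a) = 1`; `s = 0` when the strings share no characters; two empty
#' strings compare equal (similarity 1).
#'
#' @param a,b strings to compare.
#' @param normalize normalize both strings first? Default `TRUE`.
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' similarity("mama derecha", "mama parte derecha")  # 0.8
similarity <- function(a, b, normalize = TRUE) {
  if (normalize) {
    a <- normalize_text(a)
    b <- normalize_text(b)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  if (n == 0L && m == 0L) return(1)
  if (n == 0L || m == 0L) return(0)
  M <- ro_match_total(ca, cb, 1L, n, 1L, m)
  2 * M / (n + m)
}

# Total matched length of the Ratcliff-Obershelp recursion on
# a[alo..ahi] vs b[blo..bhi] (1-based inclusive bounds).
ro_match_total <- function(a, b, alo, ahi, blo, bhi) {
  if (alo > ahi || blo > bhi) return(0L)
  lcs <- longest_common_substring(a, b, alo, ahi, blo, bhi)
  if (lcs$size == 0L) return(0L)
  lcs$size +
    ro_match_total(a, b, alo, lcs$ai - 1L, blo, lcs$bi - 1L) +
    ro_match_total(a, b, lcs$ai + lcs$size, ahi, lcs$bi + lcs$size, bhi)
}

# Longest common contiguous substring within the given windows, by dynamic
# programming; ties broken by earliest start in a, then earliest in b.
longest_common_substring <- function(a, b, alo, ahi, blo, bhi) {
  best <- list(ai = alo, bi = blo, size = 0L)
  la <- ahi - alo + 1L
  lb <- bhi - blo + 1L
  prev <- integer(lb)
  for (i in seq_len(la)) {
    cur <- integer(lb)
    ai <- alo + i - 1L
    for (j in seq_len(lb)) {
      bj <- blo + j - 1L
      if (a[ai] == b[bj]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best$size) {
          best <- list(ai = ai - cur[j] + 1L, bi = bj - cur[j] + 1L,
                       size = cur[j])
        }
      }
    }
    prev <- cur
  }
  best
}
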
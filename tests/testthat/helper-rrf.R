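# Writers for tiny RRF fixtures (pipe-delimited, UMLS column order).

write_mrconso <- function(path, rows) {
  # rows: list of list(cui, lat, sab, tty, str, suppress)
  lines <- vapply(rows, function(r) {
    f <- rep("", 18)
    f[1] <- r$cui; f[2] <- r$lat; f[12] <- r$sab
    f[13] <- r$tty %||% "PT"; f[15] <- r$str
    f[17] <- r$suppress %||% "N"
    paste0(paste(f, collapse = "|"), "|")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  path
}

write_mrsty <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    f <- rep("", 6)
    f[1] <- r$cui; f[4] <- r$sty
    paste0(paste(f, collapse = "|"), "|")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  path
}

write_mrdef <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    f <- rep("", 8)
    f[1] <- r$cui; f[5] <- r$sab; f[6] <- r$def
    paste0(paste(f, collapse = "|"), "|")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  path
}
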
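# Minimal MEME motif format (version 4) reader and writer.

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms list of [pwm()] objects (sharing one background).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$bg
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6g", names(bg), bg), collapse = " "),
               ""), con)
  for (m in pwms) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$tf), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$mat)), con)
    writeLines(apply(m$mat, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal motif file
#'
#' Parses the background letter frequencies, motif ids, alternate (TF)
#' names and letter-probability matrices; probability rows are
#' renormalized to absorb printed rounding.
#'
#' @param path MEME-format file.
#' @return named list of [pwm()] objects (names are motif ids).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF ", lines[i])) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      id <- tok[2]
      tf <- if (length(tok) >= 3) tok[3] else id
      j <- i + 1L
      while (j <= length(lines) && !grepl("^letter-probability matrix",
                                          lines[j])) j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
      mat <- mat / rowSums(mat)
      out[[id]] <- pwm(mat, id = id, tf = tf, bg = bg)
      i <- j + w + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}
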
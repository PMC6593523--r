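#' Read motifs from a MEME minimal format file
#'
#' Parses the MEME minimal motif exchange format (version line, optional
#' alphabet/strands/background lines, `MOTIF` blocks with a
#' `letter-probability matrix`). Columns are renormalised to sum exactly
#' to 1 to absorb the 6-digit rounding of the text format.
#'
#' @param path file path.
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^MEME version", lines[1]))
    stopf("not a MEME minimal file (missing 'MEME version' header): %s", path)
  motifs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^MOTIF\\b", lines[i])) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      name <- if (length(toks) >= 2) toks[2] else sprintf("motif_%d", length(motifs) + 1)
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      if (j > n) stopf("MOTIF %s has no letter-probability matrix", name)
      hdr <- lines[j]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      nsites <- if (grepl("nsites=", hdr))
        as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)) else NA_integer_
      rows <- lines[(j + 1):(j + w)]
      vals <- lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      if (any(vapply(vals, length, integer(1)) != 4L))
        stopf("MOTIF %s: matrix rows must have 4 values", name)
      prob <- t(do.call(rbind, vals))          # rows A,C,G,T; cols = positions
      prob <- sweep(prob, 2, colSums(prob), "/")
      motifs[[name]] <- new_pwm(prob, name = name, nsites = nsites)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  if (!length(motifs)) stopf("no MOTIF blocks in %s", path)
  motifs
}

#' Write motifs to a MEME minimal format file
#'
#' @param pwms a `pwm` or list of `pwm` objects.
#' @param path output file path.
#' @param background length-4 background written to the header.
#' @param evalues optional numeric E-values, one per motif.
#' @export
write_meme <- function(pwms, path, background = NULL, evalues = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- check_background(background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (k in seq_along(pwms)) {
    p <- pwms[[k]]
    ev <- if (!is.null(evalues)) evalues[k] else NA_real_
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %s E= %s",
      pwm_width(p),
      ifelse(is.na(p$nsites), 20L, p$nsites),
      ifelse(is.na(ev), "0", format(ev, digits = 6))), con)
    for (j in seq_len(pwm_width(p)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         p$prob[1, j], p$prob[2, j], p$prob[3, j], p$prob[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}
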
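# MEME minimal-format motif I/O (the interchange format used by FIMO and
# the HOCOMOCO distribution).

#' Read PWMs from a MEME minimal file
#'
#' Supports the minimal format: a `MEME version` line, `ALPHABET= ACGT`,
#' an optional `Background letter frequencies` block (uniform 0.25 when
#' absent), and one `MOTIF` block per motif with its
#' `letter-probability matrix`.
#'
#' @param path MEME file.
#' @return List of [pwm()] objects in file order.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) gn_value_error("file not found: %s", path)
  lines <- trimws(readLines(path))
  if (!any(grepl("^MEME version", lines)))
    gn_format_error("%s: missing 'MEME version' line", path)
  alpha_line <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alpha_line)) {
    alpha <- gsub("\\s", "", sub("^ALPHABET=", "", alpha_line[1]))
    if (toupper(alpha) != "ACGT")
      gn_stop("gremnet_unsupported_format",
              "%s: unsupported alphabet '%s' (only ACGT)", path, alpha)
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1] + 1], "\\s+")[[1]]
    freq <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    names(freq) <- toupper(toks[c(TRUE, FALSE)])
    if (anyNA(freq) || !all(c("A", "C", "G", "T") %in% names(freq)))
      gn_parse_error("%s: malformed background frequency line", path)
    background <- unname(freq[c("A", "C", "G", "T")])
  }
  motif_at <- grep("^MOTIF\\s", lines)
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    toks <- strsplit(lines[motif_at[k]], "\\s+")[[1]]
    motif_id <- toks[2]
    alt_name <- if (length(toks) >= 3) toks[3] else NULL
    lp_rel <- grep("^letter-probability matrix",
                   lines[motif_at[k]:length(lines)])
    if (!length(lp_rel))
      gn_format_error("%s: motif %s has no letter-probability matrix",
                      path, motif_id)
    i <- motif_at[k] + lp_rel[1] - 1
    w <- suppressWarnings(as.integer(
      sub(".*w=\\s*(\\d+).*", "\\1", lines[i])))
    rows <- list(); j <- i + 1
    while (j <= length(lines) &&
           grepl("^[0-9.eE+\\-]+(\\s+[0-9.eE+\\-]+){3}$", lines[j])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1
    }
    if (!is.na(w) && length(rows) != w)
      gn_parse_error("%s: motif %s declares w=%d but has %d rows",
                     path, motif_id, w, length(rows))
    if (!length(rows))
      gn_parse_error("%s: motif %s has an empty probability matrix",
                     path, motif_id)
    probs <- do.call(rbind, rows)
    motifs[[k]] <- pwm(motif_id, probs, background = background,
                       tf_name = alt_name)
  }
  motifs
}

#' Write PWMs to a MEME minimal file
#'
#' @param motifs List of [pwm()] objects (all sharing one background).
#' @param path Output file.
#' @export
write_meme_motifs <- function(motifs, path) {
  bg <- if (length(motifs)) motifs[[1]]$background else rep(0.25, 4)
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %s C %s G %s T %s", gn_fmt(bg[1]), gn_fmt(bg[2]),
                     gn_fmt(bg[3]), gn_fmt(bg[4])), "")
  for (m in motifs) {
    lines <- c(lines,
               sprintf("MOTIF %s %s", m$motif_id, m$tf_name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m$probs)),
               vapply(seq_len(nrow(m$probs)), function(i)
                 paste(gn_fmt(m$probs[i, ]), collapse = " "), ""),
               "")
  }
  gn_write_lines(lines, path)
}
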
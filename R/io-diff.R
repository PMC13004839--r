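# Differential-expression / differential-accessibility table I/O
# (DESeq2/edgeR-style output is consumed; the fits themselves are upstream).

#' Read a differential table
#'
#' Expects columns `feature_id`, `log2fc`, `pvalue`, `padj` (names
#' remappable via `col_map`). Separator (tab or comma) is detected from the
#' header. `NA` adjusted p-values are kept as missing and treated as
#' non-significant downstream.
#'
#' @param path File to read.
#' @param kind `"rna"` or `"atac"` (recorded on the result).
#' @param col_map Optional named character vector mapping required names to
#'   the file's column names, e.g. `c(padj = "FDR")`.
#' @return Data frame `feature_id, log2fc, pvalue, padj` with attribute
#'   `kind`.
#' @export
read_diff_table <- function(path, kind = c("rna", "atac"), col_map = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) gn_value_error("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) gn_parse_error("%s: empty file", path)
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  required <- c("feature_id", "log2fc", "pvalue", "padj")
  wanted <- stats::setNames(required, required)
  if (!is.null(col_map)) wanted[names(col_map)] <- col_map
  missing <- setdiff(wanted, header)
  if (length(missing))
    gn_schema_error("%s: missing column(s) %s; found: %s", path,
                    paste(missing, collapse = ", "),
                    paste(header, collapse = ", "))
  idx <- match(wanted, header)
  body <- strsplit(lines[-1], sep, fixed = TRUE)
  n <- length(body)
  out <- data.frame(feature_id = character(n), log2fc = numeric(n),
                    pvalue = numeric(n), padj = numeric(n),
                    stringsAsFactors = FALSE)
  num_or_na <- function(s) {
    # tolerate unicode minus from copy-pasted tables
    s <- gsub("−", "-", s)
    if (s %in% c("NA", "", "NaN")) NA_real_
    else suppressWarnings(as.numeric(s))
  }
  for (i in seq_len(n)) {
    f <- body[[i]]
    if (length(f) != length(header))
      gn_parse_error("%s: ragged row at line %d", path, i + 1)
    out$feature_id[i] <- f[idx[1]]
    lfc <- num_or_na(f[idx[2]]); p <- num_or_na(f[idx[3]]); q <- num_or_na(f[idx[4]])
    if (is.na(lfc) && !f[idx[2]] %in% c("NA", "", "NaN"))
      gn_value_error("%s: non-numeric log2fc at line %d", path, i + 1)
    if (!is.na(p) && (p < 0 || p > 1))
      gn_value_error("%s: pvalue %s outside [0,1] at line %d",
                     path, gn_fmt(p), i + 1)
    if (!is.na(q) && (q < 0 || q > 1))
      gn_value_error("%s: padj %s outside [0,1] at line %d",
                     path, gn_fmt(q), i + 1)
    out$log2fc[i] <- lfc; out$pvalue[i] <- p; out$padj[i] <- q
  }
  attr(out, "kind") <- kind
  out
}

#' @rdname read_diff_table
#' @param records Data frame as returned by `read_diff_table` or
#'   [simple_differential()].
#' @export
write_diff_table <- function(records, path) {
  gn_write_lines(c("feature_id\tlog2fc\tpvalue\tpadj",
                   sprintf("%s\t%s\t%s\t%s", records$feature_id,
                           gn_fmt(records$log2fc), gn_fmt(records$pvalue),
                           gn_fmt(records$padj))), path)
}

#' Read / write FIMO-style motif hit tables
#'
#' Columns: `motif_id, sequence_name, start, stop, strand, score`
#' (`sequence_name` is a peak id; `start` is a 0-based offset within the
#' peak).
#'
#' @param path File to read or write.
#' @return Data frame with those columns.
#' @export
read_motif_hits <- function(path) {
  df <- read_tsv_checked(path, c("motif_id", "sequence_name", "start",
                                 "stop", "strand", "score"))
  df$start <- as.integer(df$start); df$stop <- as.integer(df$stop)
  df$score <- as.numeric(df$score)
  if (anyNA(df$start) || anyNA(df$stop))
    gn_parse_error("%s: non-integer hit coordinates", path)
  if (!all(df$strand %in% c("+", "-")))
    gn_value_error("%s: strand must be '+' or '-'", path)
  df
}

#' @rdname read_motif_hits
#' @param hits Data frame of motif hits.
#' @export
write_motif_hits <- function(hits, path) {
  gn_write_lines(c("motif_id\tsequence_name\tstart\tstop\tstrand\tscore",
                   sprintf("%s\t%s\t%d\t%d\t%s\t%s", hits$motif_id,
                           hits$sequence_name, as.integer(hits$start),
                           as.integer(hits$stop), hits$strand,
                           gn_fmt(hits$score))), path)
}
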
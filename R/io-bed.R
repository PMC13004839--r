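# BED peak I/O. Coordinates are 0-based half-open, exactly as in BED, and
# are kept in that convention throughout the package.

#' Read ATAC peaks from a BED file
#'
#' @param path BED file (>= 3 tab-separated columns). An optional 4th column
#'   supplies the peak id; otherwise ids are `chrom:start-end`.
#' @return A data frame with columns `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) gn_value_error("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) gn_parse_error("%s: empty BED file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  peak_id <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3)
      gn_parse_error("%s: line %d has %d columns, need >= 3", path, i, length(f))
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      gn_parse_error("%s: non-integer coordinate at line %d", path, i)
    if (s < 0) gn_value_error("%s: negative start at line %d", path, i)
    if (s >= e)
      gn_value_error("%s: empty or inverted interval [%d,%d) at line %d",
                     path, s, e, i)
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    peak_id[i] <- if (length(f) >= 4 && nzchar(f[4])) f[4] else
      sprintf("%s:%d-%d", f[1], s, e)
  }
  if (anyDuplicated(peak_id))
    gn_format_error("%s: duplicate peak ids", path)
  data.frame(peak_id = peak_id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write peaks as BED
#'
#' @param peaks Data frame with `peak_id`, `chrom`, `start`, `end`.
#' @param path Output file.
#' @export
write_bed_peaks <- function(peaks, path) {
  gn_write_lines(sprintf("%s\t%d\t%d\t%s", peaks$chrom,
                         as.integer(peaks$start), as.integer(peaks$end),
                         peaks$peak_id), path)
}

#' Read a TSS annotation table
#'
#' TSV with header `gene_id chrom tss strand`; `tss` is a 0-based
#' coordinate.
#'
#' @param path File to read.
#' @return Data frame with those columns.
#' @export
read_tss_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "tss", "strand"))
  df$tss <- suppressWarnings(as.integer(df$tss))
  if (anyNA(df$tss) || any(df$tss < 0))
    gn_value_error("%s: tss must be a non-negative integer", path)
  if (anyDuplicated(df$gene_id)) gn_format_error("%s: duplicate gene ids", path)
  if (!all(df$strand %in% c("+", "-")))
    gn_value_error("%s: strand must be '+' or '-'", path)
  df
}

#' @rdname read_tss_table
#' @param genes Data frame as returned by `read_tss_table`.
#' @export
write_tss_table <- function(genes, path) {
  gn_write_lines(c("gene_id\tchrom\ttss\tstrand",
                   sprintf("%s\t%s\t%d\t%s", genes$gene_id, genes$chrom,
                           as.integer(genes$tss), genes$strand)), path)
}

# strict header-checked TSV -> data.frame of character columns
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) gn_value_error("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 1) gn_parse_error("%s: empty file", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing))
    gn_schema_error("%s: missing column(s) %s; found: %s", path,
                    paste(missing, collapse = ", "),
                    paste(header, collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(body))
    if (length(body[[i]]) != length(header))
      gn_parse_error("%s: ragged row at line %d", path, i + 1)
  out <- as.data.frame(do.call(rbind, c(body, list(deparse.level = 0))),
                       stringsAsFactors = FALSE)
  if (!length(body)) {
    out <- as.data.frame(matrix(character(), 0, length(header)),
                         stringsAsFactors = FALSE)
  }
  names(out) <- header
  out[required]
}
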
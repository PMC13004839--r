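# Count-matrix readers/writers. Parsing is line-based so errors can name
# the offending line and cell, which read.table cannot do.

#' Read a count matrix from TSV or triplet format
#'
#' The TSV layout has a header row of gene ids and a first column of sample
#' ids. The triplet layout is a MatrixMarket-style table with header
#' `row col value` (1-based indices) and companion sample/gene id lists.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"triplet"`.
#' @param sample_ids,gene_ids For `"triplet"`: character vectors of ids, or
#'   paths to one-id-per-line text files.
#' @param layer `"counts"` (validated non-negative and integral) or
#'   `"lognorm"` (arbitrary reals, for reading back normalised matrices).
#' @return An [expression_matrix()] with the requested layer, input order
#'   preserved.
#' @export
read_counts <- function(path, format = c("tsv", "triplet"),
                        sample_ids = NULL, gene_ids = NULL,
                        layer = c("counts", "lognorm")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (!file.exists(path)) gn_value_error("file not found: %s", path)
  if (format == "tsv") read_counts_tsv(path, layer) else
    read_counts_triplet(path, sample_ids, gene_ids, layer)
}

read_counts_tsv <- function(path, layer = "counts") {
  lines <- readLines(path)
  if (length(lines) < 2) gn_parse_error("%s: need a header and >= 1 data row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_data_fields <- length(fields[[2]])
  # header may or may not carry a leading corner label for the id column
  gene_ids <- if (length(header) == n_data_fields) header[-1] else header
  if (length(gene_ids) != n_data_fields - 1)
    gn_parse_error("%s: header has %d gene ids but data rows have %d value columns",
                   path, length(gene_ids), n_data_fields - 1)
  if (anyDuplicated(gene_ids))
    gn_format_error("%s: duplicate gene ids in header", path)
  n <- length(lines) - 1
  sample_ids <- character(n)
  values <- matrix(0, n, length(gene_ids))
  for (i in seq_len(n)) {
    f <- fields[[i + 1]]
    if (length(f) != n_data_fields)
      gn_parse_error("%s: ragged row at line %d (%d fields, expected %d)",
                     path, i + 1, length(f), n_data_fields)
    sample_ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      gn_value_error("%s: non-numeric count '%s' at line %d, gene %s",
                     path, f[j + 1], i + 1, gene_ids[j])
    }
    if (layer == "counts" && any(v < 0)) {
      j <- which(v < 0)[1]
      gn_value_error("%s: negative count %s at line %d, gene %s (sample %s)",
                     path, gn_fmt(v[j]), i + 1, gene_ids[j], f[1])
    }
    values[i, ] <- v
  }
  if (anyDuplicated(sample_ids))
    gn_format_error("%s: duplicate sample ids", path)
  dimnames(values) <- list(sample_ids, gene_ids)
  expression_matrix(values, layer = layer)
}

read_id_list <- function(x, what) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) x <- readLines(x)
  if (!is.character(x) || !length(x))
    gn_value_error("triplet format requires %s as a character vector or file", what)
  x
}

read_counts_triplet <- function(path, sample_ids, gene_ids,
                                layer = "counts") {
  sample_ids <- read_id_list(sample_ids, "sample_ids")
  gene_ids <- read_id_list(gene_ids, "gene_ids")
  if (anyDuplicated(sample_ids) || anyDuplicated(gene_ids))
    gn_format_error("%s: duplicate ids in companion id lists", path)
  lines <- readLines(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]],
                                   c("row", "col", "value")))
    gn_parse_error("%s: triplet file must start with header 'row col value'", path)
  values <- matrix(0, length(sample_ids), length(gene_ids),
                   dimnames = list(sample_ids, gene_ids))
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      gn_parse_error("%s: ragged row at line %d", path, i)
    rc <- suppressWarnings(as.integer(f[1:2]))
    v <- suppressWarnings(as.numeric(f[3]))
    if (anyNA(rc) || is.na(v))
      gn_parse_error("%s: non-numeric entry at line %d", path, i)
    if (rc[1] < 1 || rc[1] > nrow(values) || rc[2] < 1 || rc[2] > ncol(values))
      gn_value_error("%s: index (%d,%d) out of range at line %d",
                     path, rc[1], rc[2], i)
    if (layer == "counts" && v < 0)
      gn_value_error("%s: negative count at line %d (row %d, col %d)",
                     path, i, rc[1], rc[2])
    values[rc[1], rc[2]] <- v
  }
  expression_matrix(values, layer = layer)
}

#' Write an expression matrix as TSV
#'
#' Counts are written as integers, log-normalised values at 12 significant
#' digits; output is byte-deterministic.
#'
#' @param x An [expression_matrix()].
#' @param path Output file.
#' @export
write_counts <- function(x, path) {
  vals <- if (em_layer(x) == "counts")
    format(round(unclass(x)), scientific = FALSE, trim = TRUE)
  else gn_fmt(unclass(x))
  vals <- matrix(vals, nrow(x), ncol(x))
  lines <- c(paste(c("sample", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], vals[i, ]), collapse = "\t"), ""))
  gn_write_lines(lines, path)
}
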
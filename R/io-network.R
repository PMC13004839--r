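# Network and prior serialisation: long-format TSV, deterministically
# ordered (tf then gene, byte order) with floats at 12 significant digits,
# so identical objects always produce byte-identical files.

#' Write an inferred network as long-format TSV
#'
#' Columns `tf, gene, weight, confidence, in_prior`; one row per edge
#' (nonzero weight or confidence), sorted by tf then gene.
#'
#' @param network A [network_matrix()].
#' @param path Output file.
#' @param prior Optional [prior_matrix()]; fills the `in_prior` column
#'   (0 everywhere when absent).
#' @export
write_network <- function(network, path, prior = NULL) {
  w <- network$weights; cf <- network$confidence
  nz <- which(w != 0 | cf != 0, arr.ind = TRUE)
  tf <- rownames(w)[nz[, 1]]; gene <- colnames(w)[nz[, 2]]
  in_prior <- rep(0L, nrow(nz))
  if (!is.null(prior)) {
    ok <- tf %in% prior$tf_ids & gene %in% prior$gene_ids
    in_prior[ok] <- as.integer(
      prior$values[cbind(match(tf[ok], prior$tf_ids),
                         match(gene[ok], prior$gene_ids))] != 0)
  }
  ord <- gn_order(tf, gene)
  rows <- sprintf("%s\t%s\t%s\t%s\t%d", tf[ord], gene[ord],
                  gn_fmt(w[nz][ord]), gn_fmt(cf[nz][ord]), in_prior[ord])
  tryCatch(
    gn_write_lines(c("tf\tgene\tweight\tconfidence\tin_prior", rows), path),
    error = function(e) gn_stop("gremnet_io_error",
                                "cannot write network to %s: %s",
                                path, conditionMessage(e)))
}

#' Read a network written by [write_network()]
#'
#' @param path File to read.
#' @param tf_ids,gene_ids Optional full id universes for the reconstructed
#'   matrices; default to the ids present in the file (byte-sorted).
#' @return A [network_matrix()].
#' @export
read_network <- function(path, tf_ids = NULL, gene_ids = NULL) {
  df <- read_tsv_checked(path, c("tf", "gene", "weight", "confidence",
                                 "in_prior"))
  w <- as.numeric(df$weight); cf <- as.numeric(df$confidence)
  if (anyNA(w) || anyNA(cf))
    gn_parse_error("%s: non-numeric weight/confidence", path)
  tf_ids <- tf_ids %||% gn_sort(unique(df$tf))
  gene_ids <- gene_ids %||% gn_sort(unique(df$gene))
  weights <- matrix(0, length(tf_ids), length(gene_ids),
                    dimnames = list(tf_ids, gene_ids))
  confidence <- weights
  i <- match(df$tf, tf_ids); j <- match(df$gene, gene_ids)
  if (anyNA(i) || anyNA(j))
    gn_value_error("%s: edge references id outside the given universe", path)
  weights[cbind(i, j)] <- w
  confidence[cbind(i, j)] <- cf
  network_matrix(weights, confidence)
}

#' Write / read a prior matrix as long-format TSV
#'
#' Columns `tf, gene, weight, n_peaks` (`n_peaks` counts the supporting
#' peaks when evidence is available, else 0).
#'
#' @param prior A [prior_matrix()].
#' @param path File to write or read.
#' @export
write_prior <- function(prior, path) {
  nz <- which(prior$values != 0, arr.ind = TRUE)
  tf <- prior$tf_ids[nz[, 1]]; gene <- prior$gene_ids[nz[, 2]]
  n_peaks <- rep(0L, nrow(nz))
  if (!is.null(prior$evidence)) {
    key <- paste(tf, gene, sep = "||")
    n_peaks <- vapply(key, function(k) {
      ev <- prior$evidence[[k]]
      if (is.null(ev)) 0L else length(unique(ev$peak_id))
    }, 0L, USE.NAMES = FALSE)
  }
  ord <- gn_order(tf, gene)
  gn_write_lines(c("tf\tgene\tweight\tn_peaks",
                   sprintf("%s\t%s\t%s\t%d", tf[ord], gene[ord],
                           gn_fmt(prior$values[nz][ord]), n_peaks[ord])),
                 path)
}

#' @rdname write_prior
#' @param tf_ids,gene_ids Optional id universes (default: ids in the file).
#' @export
read_prior <- function(path, tf_ids = NULL, gene_ids = NULL) {
  df <- read_tsv_checked(path, c("tf", "gene", "weight", "n_peaks"))
  w <- as.numeric(df$weight)
  if (anyNA(w)) gn_parse_error("%s: non-numeric prior weight", path)
  tf_ids <- tf_ids %||% gn_sort(unique(df$tf))
  gene_ids <- gene_ids %||% gn_sort(unique(df$gene))
  values <- matrix(0, length(tf_ids), length(gene_ids),
                   dimnames = list(tf_ids, gene_ids))
  values[cbind(match(df$tf, tf_ids), match(df$gene, gene_ids))] <- w
  prior_matrix(values)
}

#' Write an activity (TFA) matrix as TSV
#'
#' @param a An [activity_matrix()] (samples x TFs).
#' @param path Output file.
#' @export
write_activities <- function(a, path) {
  lines <- c(paste(c("sample", colnames(a)), collapse = "\t"),
             vapply(seq_len(nrow(a)), function(i)
               paste(c(rownames(a)[i], gn_fmt(unclass(a)[i, ])),
                     collapse = "\t"), ""))
  gn_write_lines(lines, path)
}

#' @rdname write_activities
#' @export
read_activities <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) gn_parse_error("%s: need header and >= 1 row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tf_ids <- fields[[1]][-1]
  n <- length(lines) - 1
  values <- matrix(NA_real_, n, length(tf_ids))
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i + 1]]
    if (length(f) != length(tf_ids) + 1)
      gn_parse_error("%s: ragged row at line %d", path, i + 1)
    sample_ids[i] <- f[1]
    values[i, ] <- as.numeric(f[-1])
  }
  dimnames(values) <- list(sample_ids, tf_ids)
  activity_matrix(values)
}
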
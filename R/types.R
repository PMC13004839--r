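# Domain containers. Expression and activity matrices are plain numeric
# matrices with dimnames plus a small set of attributes; priors and networks
# are lists. Orientation is fixed throughout the package:
#   expression  samples x genes
#   activities  samples x TFs
#   prior       TFs x genes
#   network     TFs x genes

#' Construct a validated expression matrix
#'
#' An expression matrix is a samples x genes numeric matrix with unique
#' sample and gene identifiers and a `layer` attribute recording whether the
#' values are raw counts or log-normalised expression.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   rownames (sample ids) and colnames (gene ids).
#' @param layer `"counts"` (non-negative integers) or `"lognorm"`.
#' @return The matrix, classed `"expr_matrix"`, with attribute `layer`.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    gn_value_error("expression values must be a numeric matrix")
  sample_ids <- rownames(values)
  gene_ids <- colnames(values)
  if (is.null(sample_ids) || is.null(gene_ids))
    gn_value_error("expression matrix requires sample rownames and gene colnames")
  if (anyDuplicated(sample_ids))
    gn_format_error("duplicate sample ids: %s",
                    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    gn_format_error("duplicate gene ids: %s",
                    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyNA(values)) gn_value_error("expression matrix contains NA")
  if (layer == "counts") {
    if (any(values < 0))
      gn_value_error("counts layer contains negative values")
    if (any(abs(values - round(values)) > 1e-8))
      gn_value_error("counts layer contains non-integral values")
  }
  structure(values, layer = layer, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d genes, layer=%s\n",
              nrow(x), ncol(x), attr(x, "layer")))
  invisible(x)
}

em_layer <- function(x) attr(x, "layer") %||% "lognorm"

#' Construct a TF x gene prior connectivity matrix
#'
#' @param values Numeric TFs x genes matrix, entries >= 0 (binary by
#'   default), with TF rownames and gene colnames.
#' @param evidence Optional named list mapping `"tf||gene"` keys to
#'   data frames of supporting (peak_id, motif_id, start, strand) evidence.
#' @return A `prior_matrix` object (list with `values`, `tf_ids`,
#'   `gene_ids`, `evidence`).
#' @export
prior_matrix <- function(values, evidence = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    gn_value_error("prior values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    gn_value_error("prior matrix requires TF rownames and gene colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    gn_format_error("duplicate ids in prior matrix")
  if (any(values < 0)) gn_value_error("prior entries must be >= 0")
  if (!is.null(evidence)) {
    nz <- which(values != 0, arr.ind = TRUE)
    keys <- paste(rownames(values)[nz[, 1]], colnames(values)[nz[, 2]],
                  sep = "||")
    if (!setequal(keys, names(evidence)))
      gn_value_error("prior evidence keys do not match nonzero entries")
  }
  structure(list(values = values, tf_ids = rownames(values),
                 gene_ids = colnames(values), evidence = evidence),
            class = "prior_matrix")
}

#' @export
print.prior_matrix <- function(x, ...) {
  cat(sprintf("<prior_matrix> %d TFs x %d genes, %d edges\n",
              nrow(x$values), ncol(x$values), sum(x$values != 0)))
  invisible(x)
}

#' Construct an inferred network (signed weights plus confidences)
#'
#' @param weights TFs x genes numeric matrix of signed regulatory weights.
#' @param confidence TFs x genes matrix in \[0, 1\]; an entry is nonzero only
#'   for TFs in the gene's best model.
#' @param diagnostics Optional per-gene diagnostics (list).
#' @return A `network_matrix` object.
#' @export
network_matrix <- function(weights, confidence, diagnostics = NULL) {
  if (!identical(dim(weights), dim(confidence)))
    gn_value_error("weights and confidence must have identical shape")
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    gn_value_error("network requires TF rownames and gene colnames")
  if (any(confidence < 0 | confidence > 1))
    gn_value_error("confidence entries must lie in [0, 1]")
  dimnames(confidence) <- dimnames(weights)
  structure(list(weights = weights, confidence = confidence,
                 tf_ids = rownames(weights), gene_ids = colnames(weights),
                 diagnostics = diagnostics),
            class = "network_matrix")
}

#' @export
print.network_matrix <- function(x, ...) {
  cat(sprintf("<network_matrix> %d TFs x %d genes, %d edges (conf > 0)\n",
              nrow(x$weights), ncol(x$weights), sum(x$confidence > 0)))
  invisible(x)
}

#' Construct an activity matrix (samples x TFs)
#'
#' @param values Numeric samples x TFs matrix with dimnames.
#' @param method_tags Named character vector, one of `"inverted"` or
#'   `"self_expression"` per TF.
#' @return The matrix, classed `"activity_matrix"`.
#' @export
activity_matrix <- function(values, method_tags = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    gn_value_error("activity matrix requires sample rownames and TF colnames")
  if (anyNA(values)) gn_value_error("activity matrix contains NaN/NA")
  if (is.null(method_tags)) {
    method_tags <- rep("inverted", ncol(values))
    names(method_tags) <- colnames(values)
  }
  stopifnot(all(method_tags %in% c("inverted", "self_expression")))
  structure(values, method_tags = method_tags,
            class = c("activity_matrix", "matrix", "array"))
}

#' Position weight matrix for a TF binding motif
#'
#' @param motif_id Motif identifier (HOCOMOCO-style ids such as
#'   `CEBPA_MOUSE.H11MO.0.A` are parsed for the TF name).
#' @param probs L x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; every row must sum to 1 within 1e-3.
#' @param background Length-4 background base frequencies (default uniform).
#' @param tf_name TF name; defaults to the part of `motif_id` before the
#'   first underscore when the id looks HOCOMOCO-like, else the id itself.
#' @return A `pwm` object.
#' @export
pwm <- function(motif_id, probs, background = rep(0.25, 4), tf_name = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4 || nrow(probs) < 1)
    gn_value_error("PWM must be an L x 4 matrix with L >= 1")
  colnames(probs) <- c("A", "C", "G", "T")
  bad <- which(abs(rowSums(probs) - 1) > 1e-3)
  if (length(bad))
    gn_value_error("PWM '%s': row %d does not sum to 1 (got %.6f)",
                   motif_id, bad[1], rowSums(probs)[bad[1]])
  if (abs(sum(background) - 1) > 1e-6)
    gn_value_error("PWM background must sum to 1")
  if (is.null(tf_name)) {
    tf_name <- if (grepl("^[^_]+_[A-Za-z]+\\.", motif_id))
      sub("_.*$", "", motif_id) else motif_id
  }
  structure(list(motif_id = motif_id, tf_name = tf_name, probs = probs,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (tf %s), length %d, consensus %s\n",
              x$motif_id, x$tf_name, nrow(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' Quality-control thresholds for single-cell count matrices
#'
#' Defaults follow common single-cell practice: cells expressing fewer than
#' 200 genes removed, genes detected in fewer than 10 cells removed, cells
#' with mitochondrial fraction above 15% removed, library-size normalisation
#' to 10,000 counts.
#'
#' @param min_genes_per_cell,min_cells_per_gene,max_mito_fraction,target_sum
#'   Filter thresholds; see Details in [qc_filter()].
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200, min_cells_per_gene = 10,
                          max_mito_fraction = 0.15, target_sum = 10000) {
  stopifnot(min_genes_per_cell > 0, min_cells_per_gene > 0,
            max_mito_fraction > 0, max_mito_fraction <= 1, target_sum > 0)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 max_mito_fraction = max_mito_fraction,
                 target_sum = target_sum),
            class = "qc_thresholds")
}

#' Thresholds for expression/accessibility concordance calls
#'
#' Defaults are the conventional cutoffs for this analysis: RNA adjusted
#' p <= 0.05 with |log2FC| >= 0.25, ATAC FDR <= 0.05 with |log2FC| >= 0.1.
#' All comparisons are inclusive at the boundary.
#'
#' @param rna_alpha,rna_lfc,atac_alpha,atac_lfc Significance and effect-size
#'   cutoffs for the RNA and ATAC sides.
#' @return A `concordance_thresholds` list.
#' @export
concordance_thresholds <- function(rna_alpha = 0.05, rna_lfc = 0.25,
                                   atac_alpha = 0.05, atac_lfc = 0.1) {
  stopifnot(rna_alpha > 0, rna_alpha <= 1, atac_alpha > 0, atac_alpha <= 1,
            rna_lfc >= 0, atac_lfc >= 0)
  structure(list(rna_alpha = rna_alpha, rna_lfc = rna_lfc,
                 atac_alpha = atac_alpha, atac_lfc = atac_lfc),
            class = "concordance_thresholds")
}
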
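# Single-cell QC and normalisation applied before network inference.

#' Quality-control filtering of a single-cell count matrix
#'
#' Three filters are applied in a fixed order, each with the conventional
#' boundary semantics:
#' 1. cells with fewer than `min_genes_per_cell` detected genes removed
#'    (a gene is "detected" when its count is > 0; a cell at exactly the
#'    threshold is retained);
#' 2. genes detected in fewer than `min_cells_per_gene` of the remaining
#'    cells removed;
#' 3. cells whose mitochondrial count fraction is strictly greater than
#'    `max_mito_fraction` removed (fraction computed on the remaining
#'    genes).
#'
#' @param x An [expression_matrix()] with layer `"counts"`
#'   (cells x genes).
#' @param mito_gene_ids Character vector of mitochondrial gene ids (may be
#'   empty, in which case the mito filter removes nothing).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `x` (the filtered counts) and `report`, a list
#'   recording cells/genes removed at each step and the final shape.
#' @export
qc_filter <- function(x, mito_gene_ids = character(),
                      thresholds = qc_thresholds()) {
  if (em_layer(x) != "counts")
    gn_value_error("qc_filter requires a counts-layer matrix")
  v <- unclass(x)
  detected_genes <- rowSums(v > 0)
  keep_cells <- detected_genes >= thresholds$min_genes_per_cell
  n_cells_min_genes <- sum(!keep_cells)
  v <- v[keep_cells, , drop = FALSE]
  if (!nrow(v))
    gn_value_error("all %d cells removed by the detected-gene filter", nrow(x))

  cells_per_gene <- colSums(v > 0)
  keep_genes <- cells_per_gene >= thresholds$min_cells_per_gene
  n_genes_removed <- sum(!keep_genes)
  v <- v[, keep_genes, drop = FALSE]
  if (!ncol(v)) gn_value_error("all genes removed by the gene filter")

  mito <- intersect(mito_gene_ids, colnames(v))
  totals <- rowSums(v)
  mito_frac <- if (length(mito)) rowSums(v[, mito, drop = FALSE]) / totals
               else rep(0, nrow(v))
  keep_mito <- mito_frac <= thresholds$max_mito_fraction
  n_cells_mito <- sum(!keep_mito)
  v <- v[keep_mito, , drop = FALSE]
  if (!nrow(v)) gn_value_error("all cells removed by the mito-fraction filter")

  list(x = expression_matrix(v, layer = "counts"),
       report = list(n_cells_in = nrow(x), n_genes_in = ncol(x),
                     n_cells_removed_min_genes = n_cells_min_genes,
                     n_genes_removed_min_cells = n_genes_removed,
                     n_cells_removed_mito = n_cells_mito,
                     n_cells_out = nrow(v), n_genes_out = ncol(v)))
}

#' Library-size normalisation and log1p transform
#'
#' Each cell's counts are scaled so its total equals `target_sum`, then
#' `log(1 + v)` is applied elementwise (natural log).
#'
#' @param x Counts-layer [expression_matrix()].
#' @param target_sum Target library size (default 10,000).
#' @return An [expression_matrix()] with layer `"lognorm"`.
#' @export
normalize_log1p <- function(x, target_sum = 10000) {
  if (em_layer(x) != "counts")
    gn_value_error("normalize_log1p requires a counts-layer matrix")
  stopifnot(target_sum > 0)
  v <- unclass(x)
  totals <- rowSums(v)
  if (any(totals == 0))
    gn_value_error("cell '%s' has zero total count",
                   rownames(v)[which(totals == 0)[1]])
  out <- log1p(v * (target_sum / totals))
  expression_matrix(out, layer = "lognorm")
}
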
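# Transcription-factor activity estimation: the expression matrix is
# modelled as X = A P with X samples x genes, A samples x TFs (latent
# activities) and P the TF x gene prior; A is recovered as the
# least-squares solution X P+ with the Moore-Penrose pseudoinverse
# computed by SVD.

#' Estimate TF activities by inverting the linear model X = A P
#'
#' Expression and prior are restricted to their shared genes; each gene is
#' optionally centered across samples (on by default: the model carries no
#' intercept, so centering absorbs baseline expression); activities are
#' the minimum-norm least-squares solution `A = X %*% pinv(P)`, with the
#' pseudoinverse computed by SVD and singular values below
#' `rtol * sigma_max` treated as zero. TFs whose prior row is empty on the
#' shared genes fall back to their own (centered) expression when the TF
#' is itself a gene in `x` (tagged `"self_expression"`), and are otherwise
#' dropped with a warning.
#'
#' @param x An [expression_matrix()] (lognorm layer; counts are
#'   library-normalised and log1p-transformed first, with a warning).
#' @param prior A [prior_matrix()].
#' @param center Center each gene across samples before inversion
#'   (default `TRUE`).
#' @param rtol Relative singular-value cutoff (default 1e-10).
#' @return An [activity_matrix()] (samples x TFs) with per-TF
#'   `method_tags`.
#' @export
estimate_tfa <- function(x, prior, center = TRUE, rtol = 1e-10) {
  stopifnot(inherits(prior, "prior_matrix"))
  if (em_layer(x) == "counts") {
    warning("estimate_tfa: counts supplied; applying normalize_log1p(target_sum = 10000)")
    x <- normalize_log1p(x)
  }
  shared <- intersect(colnames(x), prior$gene_ids)
  if (length(shared) < 2)
    gn_value_error("expression and prior share %d gene(s); need >= 2",
                   length(shared))
  xs <- unclass(x)[, shared, drop = FALSE]
  if (center) xs <- scale(xs, center = TRUE, scale = FALSE)
  p <- prior$values[, shared, drop = FALSE]

  row_live <- rowSums(p != 0) > 0
  if (!any(row_live))
    gn_value_error("prior has no nonzero rows on the shared genes")
  tags <- character(0); cols <- list()

  sv <- svd(p[row_live, , drop = FALSE])
  d_inv <- ifelse(sv$d > rtol * max(sv$d), 1 / sv$d, 0)
  pinv <- sv$v %*% (d_inv * t(sv$u))  # genes x live TFs
  a_inv <- xs %*% pinv
  colnames(a_inv) <- rownames(p)[row_live]
  for (tf in colnames(a_inv)) {
    cols[[tf]] <- a_inv[, tf]; tags[tf] <- "inverted"
  }

  for (tf in rownames(p)[!row_live]) {
    if (tf %in% colnames(x)) {
      v <- unclass(x)[, tf]
      if (center) v <- v - mean(v)
      cols[[tf]] <- v; tags[tf] <- "self_expression"
    } else {
      warning(sprintf(
        "estimate_tfa: TF '%s' has an empty prior row and no expression column; dropped",
        tf))
    }
  }
  keep <- prior$tf_ids[prior$tf_ids %in% names(cols)]
  values <- do.call(cbind, cols[keep])
  rownames(values) <- rownames(x)
  activity_matrix(values, method_tags = tags[keep])
}
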
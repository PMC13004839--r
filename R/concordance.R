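# Multi-omic concordance: genes are classified by the joint
# direction/significance of their expression change (RNA-seq) and the
# accessibility change of their best associated peak (ATAC-seq). All
# threshold comparisons are inclusive.

#' Lightweight two-group differential test
#'
#' Per gene: `log2fc = mean(a) - mean(b)` (values are assumed log2-scaled),
#' a Welch t-test p-value, and Benjamini-Hochberg adjustment across genes.
#' Genes with zero variance in both groups get p = 1 and are flagged in
#' the `flagged` column. Intended for synthetic end-to-end runs; real-data
#' differential fits come from dedicated tools upstream.
#'
#' @param x_a,x_b Lognorm-layer expression matrices (samples x genes) for
#'   the two groups, >= 2 samples each.
#' @return Data frame `feature_id, log2fc, pvalue, padj, flagged`.
#' @export
simple_differential <- function(x_a, x_b) {
  genes <- intersect(colnames(x_a), colnames(x_b))
  if (!length(genes)) gn_value_error("no shared genes")
  a <- unclass(x_a)[, genes, drop = FALSE]
  b <- unclass(x_b)[, genes, drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) gn_value_error("need >= 2 samples per group")
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  flagged <- va == 0 & vb == 0
  p[flagged] <- 1
  padj <- p.adjust(p, method = "BH")
  data.frame(feature_id = genes, log2fc = unname(ma - mb),
             pvalue = unname(p), padj = unname(padj),
             flagged = unname(flagged), stringsAsFactors = FALSE)
}

#' Aggregate peak-level differential records to genes
#'
#' Each gene receives the record of its assigned peak with the smallest
#' adjusted p-value (ties: larger |log2fc|, then lexicographically smaller
#' peak id; missing padj sorts last). Genes with no assigned peak are
#' absent from the result.
#'
#' @param peak_records Data frame of peak-level records (`feature_id` =
#'   peak id, `log2fc`, `pvalue`, `padj`).
#' @param assignment Peak-to-genes map from [assign_peaks_to_genes()].
#' @return Named list gene -> list(`log2fc`, `pvalue`, `padj`,
#'   `best_peak_id`).
#' @export
gene_level_accessibility <- function(peak_records, assignment) {
  assignment <- assignment[names(assignment) %in% peak_records$feature_id]
  n_per_peak <- lengths(assignment)
  if (!sum(n_per_peak)) return(list())
  long <- data.frame(
    peak_id = rep(names(assignment), n_per_peak),
    gene = unlist(assignment, use.names = FALSE),
    stringsAsFactors = FALSE)
  i <- match(long$peak_id, peak_records$feature_id)
  long$log2fc <- peak_records$log2fc[i]
  long$pvalue <- peak_records$pvalue[i]
  long$padj <- peak_records$padj[i]
  padj_key <- ifelse(is.na(long$padj), Inf, long$padj)
  long <- long[gn_order(long$gene, padj_key, -abs(long$log2fc),
                        long$peak_id), , drop = FALSE]
  best <- long[!duplicated(long$gene), , drop = FALSE]
  out <- lapply(seq_len(nrow(best)), function(r)
    list(log2fc = best$log2fc[r], pvalue = best$pvalue[r],
         padj = best$padj[r], best_peak_id = best$peak_id[r]))
  names(out) <- best$gene
  out
}

diff_state <- function(log2fc, padj, alpha, lfc) {
  if (is.na(padj) || padj > alpha) return("ns")
  if (!is.na(log2fc) && log2fc >= lfc) return("up")
  if (!is.na(log2fc) && log2fc <= -lfc) return("down")
  "ns"
}

CONCORDANCE_LABELS <- c(concordant_up = "concordant_up",
                        concordant_down = "concordant_down")

concordance_label <- function(rna_state, atac_state) {
  if (rna_state == "up" && atac_state == "up") "concordant_up"
  else if (rna_state == "down" && atac_state == "down") "concordant_down"
  else if (rna_state != "ns" && atac_state != "ns") "discordant"
  else if (rna_state != "ns") "expression_only"
  else if (atac_state != "ns") "accessibility_only"
  else "neither"
}

#' Classify genes into expression/accessibility concordance classes
#'
#' A gene is RNA-significant when `padj <= rna_alpha` and
#' `|log2fc| >= rna_lfc` (both inclusive; missing padj means not
#' significant), with direction from the sign of log2fc; the ATAC state is
#' defined analogously on the gene's best-peak record. The label is a pure
#' function of the two states: both up -> `concordant_up`, both down ->
#' `concordant_down`, opposite -> `discordant`, one-sided ->
#' `expression_only` / `accessibility_only`, else `neither`.
#'
#' @param rna Data frame of gene-level records (`feature_id, log2fc,
#'   pvalue, padj`); duplicate genes raise an error.
#' @param atac_by_gene Map from [gene_level_accessibility()].
#' @param thresholds A [concordance_thresholds()].
#' @return Data frame `gene_id, rna_state, atac_state, label,
#'   best_peak_id` (NA when the gene has no peak).
#' @export
classify_concordance <- function(rna, atac_by_gene,
                                 thresholds = concordance_thresholds()) {
  stopifnot(inherits(thresholds, "concordance_thresholds"))
  if (anyDuplicated(rna$feature_id))
    gn_stop("gremnet_consistency_error",
            "duplicate gene(s) in RNA table: %s",
            paste(head(unique(rna$feature_id[duplicated(rna$feature_id)]), 5),
                  collapse = ", "))
  n <- nrow(rna)
  rna_state <- character(n); atac_state <- character(n)
  label <- character(n); best_peak <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rna_state[i] <- diff_state(rna$log2fc[i], rna$padj[i],
                               thresholds$rna_alpha, thresholds$rna_lfc)
    rec <- atac_by_gene[[rna$feature_id[i]]]
    if (is.null(rec)) {
      atac_state[i] <- "ns"
    } else {
      atac_state[i] <- diff_state(rec$log2fc, rec$padj,
                                  thresholds$atac_alpha, thresholds$atac_lfc)
      best_peak[i] <- rec$best_peak_id
    }
    label[i] <- concordance_label(rna_state[i], atac_state[i])
  }
  data.frame(gene_id = rna$feature_id, rna_state = rna_state,
             atac_state = atac_state, label = label,
             best_peak_id = best_peak, stringsAsFactors = FALSE)
}

#' Per-gene Z-score matrix
#'
#' Each gene (column) is standardised across samples:
#' `(value - mean) / sd`, with sd on `n - 1` denominator. Zero-variance
#' genes become all-zero columns and are reported in attribute
#' `flagged_genes`.
#'
#' @param x An expression matrix (samples x genes), >= 2 samples.
#' @return Numeric matrix of the same shape.
#' @export
zscore_matrix <- function(x) {
  v <- unclass(x)
  if (nrow(v) < 2) gn_value_error("need >= 2 samples")
  mu <- colMeans(v)
  sdv <- apply(v, 2, sd)
  flagged <- colnames(v)[sdv == 0]
  sdv[sdv == 0] <- 1
  out <- sweep(sweep(v, 2, mu), 2, sdv, "/")
  attr(out, "flagged_genes") <- flagged
  out
}
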
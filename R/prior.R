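# Prior construction: peaks are linked to genes whose TSS lies within a
# window of the peak midpoint, and a TF-gene prior edge is created whenever
# a linked peak contains a motif occurrence for that TF.

#' Assign peaks to genes by TSS proximity
#'
#' A peak is assigned to every gene on the same chromosome whose TSS is
#' within `window_bp` of the peak midpoint (inclusive):
#' `|tss - midpoint| <= window_bp` with `midpoint = floor((start + end)/2)`.
#' Strand-agnostic.
#'
#' @param peaks Data frame with `peak_id, chrom, start, end`.
#' @param genes Data frame with `gene_id, chrom, tss`.
#' @param window_bp Window in bp (> 0).
#' @return Named list, one entry per peak (in input order), each a
#'   character vector of assigned gene ids (possibly empty).
#' @export
assign_peaks_to_genes <- function(peaks, genes, window_bp) {
  stopifnot(window_bp > 0)
  mid <- (as.numeric(peaks$start) + as.numeric(peaks$end)) %/% 2
  out <- vector("list", nrow(peaks))
  names(out) <- peaks$peak_id
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(peaks))) {
    g <- by_chrom[[peaks$chrom[i]]]
    if (is.null(g)) { out[[i]] <- character(); next }
    hit <- g[abs(genes$tss[g] - mid[i]) <= window_bp]
    out[[i]] <- genes$gene_id[hit]
  }
  out
}

#' Build a TF x gene prior from peaks, motif hits and a peak-gene map
#'
#' The entry (t, g) is nonzero iff some peak assigned to gene g contains at
#' least one hit of a motif mapping to TF t. In `"binary"` mode entries are
#' 0/1; in `"weighted"` mode they count supporting hits. Per-edge evidence
#' (peak, motif, offset, strand) is recorded. The result is independent of
#' the input ordering of peaks and hits.
#'
#' @param peaks Data frame with at least `peak_id`.
#' @param hits FIMO-style data frame (`motif_id, sequence_name, ...`);
#'   `sequence_name` must reference known peaks.
#' @param assignment Peak-to-genes map from [assign_peaks_to_genes()].
#' @param motif_to_tf Named character vector, motif id -> TF id; must cover
#'   every motif in `hits`.
#' @param tf_ids,gene_ids Id universes for the matrix shape (defaults: all
#'   mapped TFs, all assigned genes, byte-sorted).
#' @param mode `"binary"` or `"weighted"`.
#' @return A [prior_matrix()] with evidence.
#' @export
build_prior <- function(peaks, hits, assignment, motif_to_tf,
                        tf_ids = NULL, gene_ids = NULL,
                        mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(hits$sequence_name), peaks$peak_id)
  if (length(unknown))
    gn_stop("gremnet_consistency_error",
            "motif hits reference unknown peak(s): %s",
            paste(head(unknown, 5), collapse = ", "))
  unmapped <- setdiff(unique(hits$motif_id), names(motif_to_tf))
  if (length(unmapped))
    gn_stop("gremnet_consistency_error",
            "no TF mapping for motif(s): %s",
            paste(head(unmapped, 5), collapse = ", "))
  tf_ids <- tf_ids %||% gn_sort(unique(unname(motif_to_tf)))
  gene_ids <- gene_ids %||% gn_sort(unique(unlist(assignment, use.names = FALSE)))
  values <- matrix(0, length(tf_ids), length(gene_ids),
                   dimnames = list(tf_ids, gene_ids))
  evidence <- list()
  if (nrow(hits)) {
    tf_of_hit <- unname(motif_to_tf[hits$motif_id])
    genes_of_hit <- assignment[hits$sequence_name]
    n_per_hit <- lengths(genes_of_hit)
    expanded <- data.frame(
      tf = rep(tf_of_hit, n_per_hit),
      gene = unlist(genes_of_hit, use.names = FALSE),
      peak_id = rep(hits$sequence_name, n_per_hit),
      motif_id = rep(hits$motif_id, n_per_hit),
      start = rep(hits$start, n_per_hit),
      strand = rep(hits$strand, n_per_hit),
      stringsAsFactors = FALSE)
    expanded <- expanded[expanded$tf %in% tf_ids &
                           expanded$gene %in% gene_ids, , drop = FALSE]
    if (nrow(expanded)) {
      # deterministic evidence order regardless of input order
      expanded <- expanded[gn_order(expanded$tf, expanded$gene,
                                    expanded$peak_id, expanded$motif_id,
                                    expanded$start, expanded$strand), ,
                           drop = FALSE]
      key <- paste(expanded$tf, expanded$gene, sep = "||")
      counts <- table(key)
      idx <- cbind(match(expanded$tf, tf_ids), match(expanded$gene, gene_ids))
      first <- !duplicated(key)
      if (mode == "binary") {
        values[idx[first, , drop = FALSE]] <- 1
      } else {
        values[idx[first, , drop = FALSE]] <-
          as.numeric(counts[key[first]])
      }
      evidence <- split(expanded[c("peak_id", "motif_id", "start", "strand")],
                        key)
    }
  }
  prior_matrix(values, evidence = if (length(evidence)) evidence else NULL)
}

#' Build the prior encoded in a genome scaffold
#'
#' Convenience wrapper chaining [assign_peaks_to_genes()] and
#' [build_prior()] on a [generate_scaffold()] result, using the scaffold's
#' own gene and TF universes.
#'
#' @param scaffold A `genome_scaffold`.
#' @param window_bp Assignment window (defaults to the scaffold's own).
#' @param mode Passed to [build_prior()].
#' @return A [prior_matrix()] over all scaffold TFs and genes.
#' @export
scaffold_prior <- function(scaffold, window_bp = scaffold$window_bp,
                           mode = "binary") {
  assignment <- assign_peaks_to_genes(scaffold$peaks, scaffold$genes,
                                      window_bp)
  build_prior(scaffold$peaks, scaffold$motif_hits, assignment,
              scaffold$motif_to_tf,
              tf_ids = gn_sort(unique(unname(scaffold$motif_to_tf))),
              gene_ids = scaffold$genes$gene_id, mode = mode)
}
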
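# Genome scaffold generator: a synthetic chromosome with one TSS per gene,
# accessible peaks near the TSSs of true regulatory targets, and motif
# occurrences for the regulating TF planted inside those peaks. Running the
# prior-construction stage on a scaffold built with zero error rates must
# reconstruct the true prior exactly (tested as a closure property).

#' Generate a genome scaffold consistent with a truth bundle
#'
#' Genes are laid out on one synthetic chromosome with a spacing larger
#' than twice the assignment window, so a peak can only ever be linked to
#' the gene it was planted for. For every true-prior edge (tf, gene)
#' retained after applying the bundle's `prior_fnr`, a peak is placed with
#' midpoint within `window_bp` of the gene's TSS and one motif occurrence
#' of that TF inside it; decoy peaks for absent edges are added with
#' probability `prior_fpr`. With `with_sequences = TRUE`, each peak gets a
#' random ACGT sequence with the motif consensus (or its reverse
#' complement, on minus-strand hits) embedded at the hit offset.
#'
#' @param bundle A [generate_truth()] result.
#' @param window_bp Peak-to-TSS assignment window in bp (default 50,000).
#' @param seed Integer seed for layout, decoys and sequences.
#' @param peak_width Peak width in bp (default 500).
#' @param motif_length Length of each TF's generated motif (default 8).
#' @param with_sequences Generate per-peak sequences with embedded
#'   consensus sites.
#' @param chrom_length Optional chromosome length; an error is raised when
#'   it is too small for the required gene spacing.
#' @return A `genome_scaffold` list: `chrom_lengths`, `genes`, `peaks`,
#'   `motif_hits` (FIMO-style data frame, 0-based half-open offsets within
#'   peaks), `motifs` (list of [pwm()]), `motif_to_tf`, `sequences`,
#'   `window_bp`, and `planted` (the per-peak edge audit table).
#' @export
generate_scaffold <- function(bundle, window_bp = 50000, seed = 1,
                              peak_width = 500, motif_length = 8,
                              with_sequences = FALSE, chrom_length = NULL) {
  stopifnot(inherits(bundle, "truth_bundle"), window_bp > 0,
            peak_width > 2 * motif_length)
  p <- bundle$params
  tf_ids <- bundle$prior_true$tf_ids
  gene_ids <- bundle$prior_true$gene_ids
  half_w <- peak_width %/% 2

  spacing <- 2L * as.integer(window_bp) + 4L * as.integer(peak_width) + 1000L
  offset <- as.integer(window_bp) + as.integer(peak_width) + 100L
  needed <- offset + spacing * length(gene_ids) + as.integer(window_bp)
  if (!is.null(chrom_length)) {
    if (chrom_length < needed)
      gn_layout_error(paste0(
        "chromosome length %d too small for %d genes at window %d; ",
        "need >= %d (use a larger chromosome)"),
        chrom_length, length(gene_ids), window_bp, needed)
    needed <- as.integer(chrom_length)
  }
  genes <- data.frame(gene_id = gene_ids, chrom = "chr1",
                      tss = offset + spacing * (seq_along(gene_ids) - 1L),
                      strand = "+", stringsAsFactors = FALSE)

  gn_set_seed(seed)
  # per-TF informative motif: one dominant base per position
  motifs <- lapply(tf_ids, function(tf) {
    dom <- sample.int(4, motif_length, replace = TRUE)
    probs <- matrix(0.02, motif_length, 4)
    probs[cbind(seq_len(motif_length), dom)] <- 0.94
    pwm(sprintf("%s_MOUSE.H11MO.0.A", tf), probs, tf_name = tf)
  })
  names(motifs) <- vapply(motifs, `[[`, "", "motif_id")
  motif_to_tf <- stats::setNames(tf_ids, names(motifs))

  support <- bundle$prior_true$values != 0
  edges <- which(support, arr.ind = TRUE)
  keep <- runif(nrow(edges)) >= p$prior_fnr
  absent <- which(!support, arr.ind = TRUE)
  decoy <- runif(nrow(absent)) < p$prior_fpr
  plan <- rbind(
    data.frame(tf = tf_ids[edges[keep, 1]], gene = gene_ids[edges[keep, 2]],
               is_decoy = rep(FALSE, sum(keep)), stringsAsFactors = FALSE),
    data.frame(tf = tf_ids[absent[decoy, 1]],
               gene = gene_ids[absent[decoy, 2]],
               is_decoy = rep(TRUE, sum(decoy)), stringsAsFactors = FALSE))

  n <- nrow(plan)
  tss <- genes$tss[match(plan$gene, genes$gene_id)]
  max_d <- as.integer(window_bp) - half_w
  d <- if (n) sample.int(2L * max_d + 1L, n, replace = TRUE) - max_d - 1L
       else integer()
  start <- tss + d - half_w
  peaks <- data.frame(peak_id = sprintf("pk%05d", seq_len(n)),
                      chrom = "chr1", start = start,
                      end = start + as.integer(peak_width),
                      stringsAsFactors = FALSE)
  hit_off <- if (n) sample.int(peak_width - motif_length + 1L, n,
                               replace = TRUE) - 1L else integer()
  hit_strand <- if (n) c("+", "-")[sample.int(2L, n, replace = TRUE)]
                else character()
  motif_ids <- names(motifs)[match(plan$tf, tf_ids)]
  hits <- data.frame(motif_id = motif_ids, sequence_name = peaks$peak_id,
                     start = hit_off, stop = hit_off + motif_length,
                     strand = hit_strand,
                     score = vapply(motifs[motif_ids], pwm_max_score, 0),
                     stringsAsFactors = FALSE)
  plan$peak_id <- peaks$peak_id

  sequences <- NULL
  if (with_sequences && n) {
    bases <- c("A", "C", "G", "T")
    sequences <- vapply(seq_len(n), function(i) {
      s <- sample(bases, peak_width, replace = TRUE)
      cons <- strsplit(pwm_consensus(motifs[[motif_ids[i]]]), "")[[1]]
      if (hit_strand[i] == "-") cons <- rev_comp_chars(cons)
      s[(hit_off[i] + 1):(hit_off[i] + motif_length)] <- cons
      paste(s, collapse = "")
    }, "")
    names(sequences) <- peaks$peak_id
  }

  # construction audit: hits inside peaks, TSSs on the chromosome
  stopifnot(all(hits$start >= 0),
            all(hits$stop <= peaks$end - peaks$start),
            all(genes$tss >= 0), all(genes$tss < needed),
            all(peaks$start >= 0), all(peaks$end <= needed))
  structure(list(chrom_lengths = c(chr1 = needed), genes = genes,
                 peaks = peaks, motif_hits = hits, motifs = motifs,
                 motif_to_tf = motif_to_tf, sequences = sequences,
                 window_bp = as.integer(window_bp), planted = plan),
            class = "genome_scaffold")
}

rev_comp_chars <- function(x) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

#' Write a bundle and scaffold as a file-based fixture set
#'
#' Emits the standard-format files every pipeline stage consumes: WT/KO
#' counts TSV, peak BED, TSS TSV, MEME motifs, FIMO-style hit TSV, the
#' motif-to-TF map, the true prior and network, and the true activity
#' matrices.
#'
#' @param bundle A [generate_truth()] result.
#' @param scaffold A [generate_scaffold()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_set <- function(bundle, scaffold, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  write_counts(generate_expression(bundle, "wt"), path("counts_wt.tsv"))
  write_counts(generate_expression(bundle, "ko"), path("counts_ko.tsv"))
  write_bed_peaks(scaffold$peaks, path("peaks.bed"))
  write_tss_table(scaffold$genes, path("tss.tsv"))
  write_meme_motifs(scaffold$motifs, path("motifs.meme"))
  write_motif_hits(scaffold$motif_hits, path("motif_hits.tsv"))
  gn_write_lines(c("motif_id\ttf",
                   sprintf("%s\t%s", names(scaffold$motif_to_tf),
                           scaffold$motif_to_tf)), path("motif_to_tf.tsv"))
  write_prior(bundle$prior_true, path("prior_true.tsv"))
  write_network(bundle$w_true, path("network_true.tsv"),
                prior = bundle$prior_true)
  write_activities(bundle$a_wt, path("tfa_wt_true.tsv"))
  write_activities(bundle$a_ko, path("tfa_ko_true.tsv"))
  invisible(stats::setNames(
    as.list(path(c("counts_wt.tsv", "counts_ko.tsv", "peaks.bed", "tss.tsv",
                   "motifs.meme", "motif_hits.tsv", "motif_to_tf.tsv",
                   "prior_true.tsv", "network_true.tsv", "tfa_wt_true.tsv",
                   "tfa_ko_true.tsv"))),
    c("counts_wt", "counts_ko", "peaks", "tss", "motifs", "motif_hits",
      "motif_to_tf", "prior_true", "network_true", "tfa_wt", "tfa_ko")))
}
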
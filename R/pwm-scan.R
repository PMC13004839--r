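# PWM scoring and scanning. Scores are per-position log2 likelihood ratios
# against the background, with a pseudocount of 1e-3 added to the PWM
# probabilities (rows renormalised), so a uniform motif scores exactly 0
# everywhere. P-values come from an exact dynamic program over the score
# distribution under the background model, with scores discretised to
# 1e-3 bins.

PWM_SCORE_BIN <- 1e-3
PWM_PVALUE_MAX_LEN <- 20L

# L x 4 matrix of per-position log2-odds scores
pwm_log_odds <- function(pwm) {
  pr <- pwm$probs + PWM_SCORE_BIN
  pr <- pr / rowSums(pr)
  log2(pr / matrix(pwm$background, nrow(pr), 4, byrow = TRUE))
}

#' Maximum attainable score and consensus of a PWM
#'
#' @param pwm A [pwm()] object.
#' @return `pwm_max_score`: the score of the consensus sequence;
#'   `pwm_consensus`: the consensus string (argmax base per position, ties
#'   to the earlier base in ACGT order).
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm_log_odds(pwm), 1, max))

#' @rdname pwm_max_score
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Exact score distribution of a PWM under its background
#'
#' Dynamic program over discretised per-position scores: position scores
#' are rounded to integer multiples of 1e-3 and convolved under the
#' background base distribution. Limited to motifs of length <= 20 (the
#' table grows linearly with length times score range).
#'
#' @param pwm A [pwm()] object with length <= 20.
#' @return List with `scores` (ascending, in score units), `prob` (exact
#'   probability of each score) and `tail` (P(score >= s)).
#' @export
pwm_score_distribution <- function(pwm) {
  L <- nrow(pwm$probs)
  if (L > PWM_PVALUE_MAX_LEN)
    gn_value_error(paste0(
      "p-value computation supports motif length <= %d (got %d); ",
      "use a score threshold for longer motifs"), PWM_PVALUE_MAX_LEN, L)
  k <- round(pwm_log_odds(pwm) / PWM_SCORE_BIN)  # integer bin per (pos, base)
  lo <- cumsum(apply(k, 1, min)); hi <- cumsum(apply(k, 1, max))
  dp <- numeric(hi[L] - lo[L] + 1)  # index = score - lo, 1-based
  # position 1
  for (b in 1:4)
    dp[k[1, b] - lo[1] + 1] <- dp[k[1, b] - lo[1] + 1] + pwm$background[b]
  span_lo <- lo[1]
  if (L > 1) for (i in 2:L) {
    new <- numeric(hi[i] - lo[i] + 1)
    nz <- which(dp != 0)
    for (b in 1:4) {
      idx <- nz + (span_lo + k[i, b] - lo[i])
      new[idx] <- new[idx] + dp[nz] * pwm$background[b]
    }
    dp <- new; span_lo <- lo[i]
  }
  nz <- which(dp != 0)
  bins <- nz - 1 + span_lo
  prob <- dp[nz]
  list(scores = bins * PWM_SCORE_BIN, bins = bins, prob = prob,
       tail = rev(cumsum(rev(prob))))
}

# exact tail p-value P(score bin >= bin) for integer score bins
pwm_bin_pvalue <- function(dist, bin) {
  i <- findInterval(bin - 0.5, dist$bins) + 1  # first distribution bin >= bin
  out <- numeric(length(bin))
  inside <- i <= length(dist$bins)
  out[inside] <- dist$tail[i[inside]]
  out
}

#' Scan a sequence with a PWM
#'
#' Scans both strands; at each position the reported score is the better of
#' the forward and reverse-complement scores (FIMO-like behaviour). `N`
#' bases contribute a score of 0 (background behaviour). Exactly one of
#' `score` or `pvalue` must be given as the hit threshold; in p-value mode
#' the score cutoff is derived from the exact background score
#' distribution and each hit also carries its exact p-value.
#'
#' @param sequence ACGT string (N allowed).
#' @param pwm A [pwm()] object.
#' @param score Minimum score for a hit (inclusive).
#' @param pvalue Maximum p-value for a hit (inclusive); requires motif
#'   length <= 20.
#' @param sequence_name Value for the `sequence_name` column (default
#'   `"seq"`).
#' @return FIMO-style data frame: `motif_id, sequence_name, start, stop,
#'   strand, score` (+ `pvalue` in p-value mode); `start` is a 0-based
#'   offset, `stop` is `start + motif length` (half-open).
#' @export
scan_pwm <- function(sequence, pwm, score = NULL, pvalue = NULL,
                     sequence_name = "seq") {
  if (is.null(score) == is.null(pvalue))
    gn_value_error("supply exactly one of 'score' or 'pvalue'")
  chars <- strsplit(toupper(sequence), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code))
    gn_value_error("invalid character '%s' in sequence (only ACGTN)",
                   chars[which(is.na(code))[1]])
  S <- pwm_log_odds(pwm)
  S <- cbind(S, N = 0)  # N scores as background
  L <- nrow(S)
  n_pos <- length(code) - L + 1
  if (n_pos < 1)
    return(empty_hits(pvalue_mode = !is.null(pvalue)))
  # reverse strand: complement scores, reversed positions
  S_rc <- S[L:1, c(4, 3, 2, 1, 5), drop = FALSE]
  fwd <- rev <- numeric(n_pos)
  for (i in seq_len(L)) {
    b <- code[i:(i + n_pos - 1)]
    fwd <- fwd + S[i, b]
    rev <- rev + S_rc[i, b]
  }
  best <- pmax(fwd, rev)
  strand_best <- ifelse(fwd >= rev, "+", "-")
  if (!is.null(pvalue)) {
    # p-value mode works on the same integer score bins as the DP, so hit
    # p-values and the threshold are exactly consistent with the
    # distribution
    dist <- pwm_score_distribution(pwm)
    k <- round(pwm_log_odds(pwm) / PWM_SCORE_BIN)
    k <- cbind(k, N = 0)
    k_rc <- k[L:1, c(4, 3, 2, 1, 5), drop = FALSE]
    fwd_b <- rev_b <- numeric(n_pos)
    for (i in seq_len(L)) {
      b <- code[i:(i + n_pos - 1)]
      fwd_b <- fwd_b + k[i, b]
      rev_b <- rev_b + k_rc[i, b]
    }
    best_b <- pmax(fwd_b, rev_b)
    pvals <- pwm_bin_pvalue(dist, best_b)
    hit_at <- which(pvals <= pvalue)
    out <- data.frame(motif_id = rep(pwm$motif_id, length(hit_at)),
                      sequence_name = rep(sequence_name, length(hit_at)),
                      start = hit_at - 1L, stop = hit_at - 1L + L,
                      strand = strand_best[hit_at], score = best[hit_at],
                      pvalue = pvals[hit_at], stringsAsFactors = FALSE)
    return(out)
  }
  hit_at <- which(best >= score - 1e-12)
  data.frame(motif_id = rep(pwm$motif_id, length(hit_at)),
             sequence_name = rep(sequence_name, length(hit_at)),
             start = hit_at - 1L, stop = hit_at - 1L + L,
             strand = strand_best[hit_at], score = best[hit_at],
             stringsAsFactors = FALSE)
}

empty_hits <- function(pvalue_mode = FALSE) {
  out <- data.frame(motif_id = character(), sequence_name = character(),
                    start = integer(), stop = integer(),
                    strand = character(), score = numeric(),
                    stringsAsFactors = FALSE)
  if (pvalue_mode) out$pvalue <- numeric()
  out
}
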
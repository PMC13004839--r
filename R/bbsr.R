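# Per-gene network inference by exhaustive best-subset regression of
# expression on TF activities, scored by BIC with exponential model
# weights. Candidates are capped by a correlation-based preselection so
# enumeration stays bounded (2^n_preselect models per gene).

#' Configuration for best-subset network inference
#'
#' @param n_preselect Candidate TFs kept per gene (enumeration bound;
#'   `1 <= max_subset_size <= n_preselect <= 20`).
#' @param max_subset_size Largest model size enumerated (default
#'   `n_preselect`).
#' @param prior_inclusion_bonus BIC reduction per prior-supported TF in a
#'   model (default 0 = prior does not bias scoring, it only orders
#'   preselection).
#' @param ic Information criterion; only `"bic"` is implemented.
#' @return A `bbsr_config` list.
#' @export
bbsr_config <- function(n_preselect = 10, max_subset_size = n_preselect,
                        prior_inclusion_bonus = 0, ic = "bic") {
  ic <- match.arg(ic, "bic")
  if (n_preselect < 1 || n_preselect > 20)
    gn_value_error("n_preselect must lie in [1, 20] (enumeration bound)")
  if (max_subset_size < 1 || max_subset_size > n_preselect)
    gn_value_error("max_subset_size must lie in [1, n_preselect]")
  stopifnot(prior_inclusion_bonus >= 0)
  structure(list(n_preselect = as.integer(n_preselect),
                 max_subset_size = as.integer(max_subset_size),
                 prior_inclusion_bonus = prior_inclusion_bonus, ic = ic),
            class = "bbsr_config")
}

#' Preselect candidate TFs for one gene
#'
#' Returns up to `n_preselect` TF ids: prior-supported TFs first, ordered
#' by decreasing absolute Pearson correlation with the gene's expression,
#' then the remaining TFs by decreasing |correlation|. Exact correlation
#' ties break lexicographically (byte order). A TF whose id equals the
#' gene's id (self-regulation) is excluded.
#'
#' @param y Numeric expression vector for the gene (length = samples).
#' @param a An [activity_matrix()].
#' @param prior_col Named numeric/logical vector of prior support for this
#'   gene (names = TF ids), or `NULL` for no prior.
#' @param cfg A [bbsr_config()].
#' @param gene_id Optional gene id used to exclude the self-edge.
#' @return Character vector of TF ids (possibly empty, with a warning, for
#'   zero-variance `y`).
#' @export
preselect_predictors <- function(y, a, prior_col = NULL,
                                 cfg = bbsr_config(), gene_id = NULL) {
  if (length(y) < 3) gn_value_error("need >= 3 samples")
  if (sd(y) == 0) {
    warning("preselect_predictors: zero-variance response; no candidates")
    return(character())
  }
  tfs <- colnames(a)
  if (!is.null(gene_id)) tfs <- setdiff(tfs, gene_id)
  if (!length(tfs)) return(character())
  cors <- abs(suppressWarnings(cor(y, unclass(a)[, tfs, drop = FALSE])))[1, ]
  cors[is.na(cors)] <- 0
  in_prior <- if (is.null(prior_col)) rep(FALSE, length(tfs)) else {
    pv <- prior_col[tfs]
    !is.na(pv) & pv != 0
  }
  ord <- gn_order(!in_prior, -cors, tfs)
  head(tfs[ord], cfg$n_preselect)
}

#' Score one candidate subset by ordinary least squares and BIC
#'
#' `y` and the selected activity columns are centered, the subset is fit
#' by OLS (QR), and `bic = n * log(rss/n) + k * log(n)` with `k` the
#' subset size; the empty subset scores the null model
#' (`rss = sum((y - mean(y))^2)`, `k = 0`). Inside the BIC, rss is floored
#' at `1e-12 * sum((y - mean(y))^2)` so exact fits are ranked by the
#' penalty. Collinear designs fall back to ridge (lambda 1e-8) and are
#' flagged via attribute `ridge_used`.
#'
#' @param y Response vector.
#' @param z Numeric matrix of candidate activity columns.
#' @param subset Integer or character indices of `z` columns to fit.
#' @return List `rss`, `k`, `bic`, `betas` (named OLS coefficients).
#' @export
score_subset <- function(y, z, subset) {
  z <- as.matrix(z)
  if (is.character(subset)) subset <- match(subset, colnames(z))
  n <- length(y)
  k <- length(subset)
  if (n <= k + 1) gn_value_error("need n > |subset| + 1")
  yc <- y - mean(y)
  syy <- sum(yc^2)
  floor_ <- max(syy * 1e-12, 1e-300)
  ridge_used <- FALSE
  if (k == 0) {
    rss <- syy
    betas <- numeric(0)
  } else {
    zc <- scale(z[, subset, drop = FALSE], center = TRUE, scale = FALSE)
    fit <- lm.fit(zc, yc)
    if (fit$rank < k) {
      betas <- drop(solve(crossprod(zc) + diag(1e-8, k), crossprod(zc, yc)))
      rss <- sum((yc - zc %*% betas)^2)
      ridge_used <- TRUE
    } else {
      betas <- fit$coefficients
      rss <- sum(fit$residuals^2)
    }
    names(betas) <- colnames(z)[subset]
  }
  out <- list(rss = rss, k = k,
              bic = n * log(max(rss, floor_) / n) + k * log(n),
              betas = betas)
  attr(out, "ridge_used") <- ridge_used
  out
}

#' Infer one gene's regulators by exhaustive best-subset regression
#'
#' All subsets of the preselected candidates up to `max_subset_size` are
#' enumerated (size order, then lexicographic over byte-sorted candidate
#' ids) and scored by BIC, minus `prior_inclusion_bonus` per
#' prior-supported member. The best model minimises this effective BIC
#' (ties resolved to the smaller, then lexicographically earlier subset by
#' the enumeration order). Reported weights are model-averaged over all
#' enumerated subsets with weights proportional to
#' `exp(-(bic - bic_min)/2)`; the confidence of a best-model TF t is
#' `max(0, 1 - rss_best / rss_best_without_t)` and exactly 0 for TFs
#' outside the best model.
#'
#' @inheritParams preselect_predictors
#' @return List with named `weights` and `confidence` vectors over all TFs
#'   of `a`, and `diagnostics` (best subset, BIC, rss, subset size, ridge
#'   flag).
#' @export
bbsr_gene <- function(y, a, prior_col = NULL, cfg = bbsr_config(),
                      gene_id = NULL) {
  tfs <- colnames(a)
  zero <- stats::setNames(numeric(length(tfs)), tfs)
  cand <- preselect_predictors(y, a, prior_col, cfg, gene_id)
  if (!length(cand))
    return(list(weights = zero, confidence = zero,
                diagnostics = list(best_subset = character(),
                                   best_bic = NA_real_, best_rss = NA_real_,
                                   subset_size = 0L, ridge_used = FALSE)))
  cand <- gn_sort(cand)  # deterministic enumeration order
  yc <- y - mean(y)
  zc <- scale(unclass(a)[, cand, drop = FALSE], center = TRUE, scale = FALSE)
  flags <- if (is.null(prior_col)) integer(length(cand)) else {
    pv <- prior_col[cand]
    as.integer(!is.na(pv) & pv != 0)
  }
  res <- .bbsr_enumerate(zc, yc, flags, cfg$prior_inclusion_bonus,
                         cfg$max_subset_size)
  weights <- confidence <- zero
  weights[cand] <- res$beta_avg
  confidence[cand] <- res$confidence
  list(weights = weights, confidence = confidence,
       diagnostics = list(best_subset = cand[res$best_subset],
                          best_bic = res$best_bic, best_rss = res$best_rss,
                          subset_size = length(res$best_subset),
                          ridge_used = res$ridge_used))
}

#' Infer a TF-to-gene regulatory network
#'
#' Applies [bbsr_gene()] independently to every gene of `x`, regressing
#' its (centered) expression on the TF activity matrix. Deterministic:
#' no randomness is involved and all tie-breaks are fixed.
#'
#' @param x An [expression_matrix()] (samples x genes).
#' @param a An [activity_matrix()] sharing samples with `x`.
#' @param prior Optional [prior_matrix()] used for preselection ordering
#'   and the BIC bonus.
#' @param cfg A [bbsr_config()].
#' @return A [network_matrix()] (TFs x genes) with per-gene diagnostics.
#' @export
infer_network <- function(x, a, prior = NULL, cfg = bbsr_config()) {
  samples <- intersect(rownames(x), rownames(a))
  if (length(samples) < 3)
    gn_value_error("expression and activities share %d sample(s); need >= 3",
                   length(samples))
  xs <- unclass(x)[samples, , drop = FALSE]
  as_ <- activity_matrix(unclass(a)[samples, , drop = FALSE],
                         attr(a, "method_tags"))
  genes <- colnames(xs); tfs <- colnames(as_)
  weights <- confidence <- matrix(0, length(tfs), length(genes),
                                  dimnames = list(tfs, genes))
  diagnostics <- vector("list", length(genes)); names(diagnostics) <- genes
  for (g in genes) {
    prior_col <- if (!is.null(prior) && g %in% prior$gene_ids)
      stats::setNames(prior$values[, g], prior$tf_ids) else NULL
    fit <- bbsr_gene(xs[, g], as_, prior_col, cfg, gene_id = g)
    weights[, g] <- fit$weights
    confidence[, g] <- fit$confidence
    diagnostics[[g]] <- fit$diagnostics
  }
  network_matrix(weights, confidence, diagnostics = diagnostics)
}

#' Summarise TF out-degrees in an inferred network
#'
#' Counts, per TF, the genes whose edge confidence is positive and at
#' least `min_conf`, and returns the TFs regulating at least `min_targets`
#' genes, ranked by target count from highest to lowest (ties in byte
#' order of the TF id).
#'
#' @param net A [network_matrix()].
#' @param min_conf Minimum edge confidence in `[0, 1]`.
#' @param min_targets Minimum number of targets for a TF to be reported
#'   (default 4).
#' @return Data frame `tf`, `n_targets`.
#' @export
summarize_tf_degrees <- function(net, min_conf = 0, min_targets = 4) {
  stopifnot(min_conf >= 0, min_conf <= 1)
  is_edge <- net$confidence > 0 & net$confidence >= min_conf
  counts <- rowSums(is_edge)
  keep <- counts >= min_targets
  tf <- net$tf_ids[keep]; n <- unname(counts[keep])
  ord <- gn_order(-n, tf)
  data.frame(tf = tf[ord], n_targets = as.integer(n[ord]),
             stringsAsFactors = FALSE)
}

#' Average precision of an edge ranking against the true support
#'
#' Standard average precision (area under the precision-recall curve
#' evaluated at every distinct score threshold); tied scores enter as one
#' block.
#'
#' @param scores Numeric scores (higher = more confident).
#' @param labels Logical/0-1 true-edge indicators, same length.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0) gn_value_error("no positive labels")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  block_last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(l)[block_last]
  fp <- cumsum(!l)[block_last]
  prec <- tp / (tp + fp)
  d_tp <- diff(c(0, tp))
  sum(d_tp * prec) / n_pos
}
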
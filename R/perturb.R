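# In-silico knockout validation: knockout-condition TF activities are
# multiplied by the wild-type network and the predicted expression is
# scored against the observed knockout expression by R-squared.

#' Simulate expression from activities and a network
#'
#' Edges with confidence below `conf_threshold` are zeroed, then
#' `X_hat = A %*% W` over the shared TFs.
#'
#' @param a_cond An [activity_matrix()] (samples x TFs) for the condition
#'   of interest.
#' @param net A [network_matrix()] (the wild-type network).
#' @param conf_threshold Minimum edge confidence in `[0, 1]` (default 0 =
#'   use every inferred edge).
#' @return An [expression_matrix()] (layer `"lognorm"`; values live in the
#'   gene-centered space the network was fit in).
#' @export
simulate_expression <- function(a_cond, net, conf_threshold = 0) {
  stopifnot(inherits(net, "network_matrix"),
            conf_threshold >= 0, conf_threshold <= 1)
  shared <- intersect(colnames(a_cond), net$tf_ids)
  if (!length(shared))
    gn_value_error("activities and network share no TFs")
  w <- net$weights[shared, , drop = FALSE]
  w[net$confidence[shared, , drop = FALSE] < conf_threshold] <- 0
  x_hat <- unclass(a_cond)[, shared, drop = FALSE] %*% w
  expression_matrix(x_hat, layer = "lognorm")
}

#' Coefficient of determination between observed and simulated expression
#'
#' Matrices are inner-joined on sample and gene ids; observed values are
#' centered per gene and
#' `R^2 = 1 - sum((obs - hat)^2) / sum((obs - mean_g(obs))^2)`
#' is computed over all matched entries (`"global"`) or per gene column
#' (`"per_gene"`). Genes with zero observed variance are excluded and
#' counted. R-squared never exceeds 1 and is negative for predictors worse
#' than the per-gene mean.
#'
#' @param x_obs,x_hat Expression matrices (samples x genes).
#' @param mode `"global"` or `"per_gene"`.
#' @param center_hat Also center `x_hat` per gene before comparison (used
#'   when the prediction was fit in gene-centered space).
#' @return A single number (`"global"`) or a named per-gene vector, with
#'   attribute `n_genes_used`.
#' @export
r_squared <- function(x_obs, x_hat, mode = c("global", "per_gene"),
                      center_hat = FALSE) {
  mode <- match.arg(mode)
  genes <- intersect(colnames(x_obs), colnames(x_hat))
  samples <- intersect(rownames(x_obs), rownames(x_hat))
  if (!length(genes) || length(samples) < 2)
    gn_value_error("need shared genes and >= 2 shared samples")
  obs <- unclass(x_obs)[samples, genes, drop = FALSE]
  hat <- unclass(x_hat)[samples, genes, drop = FALSE]
  mu <- colMeans(obs)
  obs <- sweep(obs, 2, mu)
  if (center_hat) hat <- scale(hat, center = TRUE, scale = FALSE)
  else hat <- sweep(hat, 2, mu)
  sst_g <- colSums(obs^2)
  use <- sst_g > 0
  if (!any(use)) gn_value_error("all shared genes have zero observed variance")
  sse_g <- colSums((obs - hat)^2)
  out <- if (mode == "global")
    1 - sum(sse_g[use]) / sum(sst_g[use])
  else stats::setNames(1 - sse_g[use] / sst_g[use], genes[use])
  attr(out, "n_genes_used") <- sum(use)
  out
}

#' Simulate a perturbation and score it against observation
#'
#' Chains [simulate_expression()] and [r_squared()]: the condition TFA is
#' multiplied by the (wild-type) network and the prediction is scored
#' against the observed condition expression. Both matrices are compared
#' in per-gene-centered space, since inferred networks are fit on centered
#' expression.
#'
#' @param x_obs Observed condition expression.
#' @param a_cond Condition activity matrix.
#' @param net Wild-type [network_matrix()].
#' @param conf_threshold Minimum edge confidence (default 0).
#' @return List: `x_hat`, `r2_global`, `r2_per_gene`, `r2_quantiles`
#'   (per-gene 5/25/50/75/95% quantiles), `n_genes_used`.
#' @export
evaluate_perturbation <- function(x_obs, a_cond, net, conf_threshold = 0) {
  x_hat <- simulate_expression(a_cond, net, conf_threshold)
  r2g <- r_squared(x_obs, x_hat, "global", center_hat = TRUE)
  r2p <- r_squared(x_obs, x_hat, "per_gene", center_hat = TRUE)
  list(x_hat = x_hat,
       r2_global = as.numeric(r2g),
       r2_per_gene = r2p,
       r2_quantiles = quantile(r2p, c(0.05, 0.25, 0.5, 0.75, 0.95),
                               names = TRUE),
       n_genes_used = attr(r2g, "n_genes_used"))
}
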
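# Synthetic ground-truth generator. The generative model is the one the
# inference assumes: expression = activities x network + noise, with a
# knockout condition obtained by zeroing the perturbed TFs' activity
# columns. All randomness flows from a single integer seed through a fixed
# RNG (Mersenne-Twister / inversion / rejection sampling), so a bundle is
# bit-identical across platforms.

#' Simulation parameters for the synthetic regulatory system
#'
#' Defaults describe a small but identifiable system: 20 TFs, 400 genes,
#' 300 samples per condition, 3 regulators per gene, unit-scale edge
#' weights, Gaussian activities, additive Gaussian observation noise of
#' sd 0.25, and a prior corrupted at a 2% false-edge and 20% missed-edge
#' rate. Edges are activating with probability `activation_prob` (default
#' 0.8, an activation-dominant regime; an unsigned motif prior carries no
#' sign information, so sign-balanced systems are not identifiable through
#' it — see the methods vignette).
#'
#' @param n_tf,n_gene,n_sample_wt,n_sample_ko System dimensions.
#' @param edges_per_gene True regulators per gene (must be <= `n_tf`).
#' @param weight_scale Scale of edge-weight magnitudes.
#' @param weight_model `"signed_uniform"` (magnitude ~ U(0.5, 1.5) x scale,
#'   sign activating with probability `activation_prob`) or `"unit"`
#'   (all weights exactly +1, the exact-model regime in which the binary
#'   prior equals the network and the linear inversion is exact).
#' @param activation_prob Probability an edge is activating (sign +1).
#' @param activity_model `"gaussian"` (N(0,1), mean-zero: knockouts alter
#'   covariance but not mean expression) or `"lognormal"` (logN(0,1),
#'   positive mean: knockouts shift target-gene means, the regime for
#'   differential-expression experiments).
#' @param noise_sd Sd of additive Gaussian observation noise on the latent
#'   expression.
#' @param count_model `"none"` (return the latent matrix, layer lognorm),
#'   `"poisson"` or `"negbin"` (draw counts with mean `exp(min(latent,
#'   10))`, a clipped log link).
#' @param nb_dispersion Negative-binomial size parameter.
#' @param prior_fpr,prior_fnr False-positive / false-negative edge rates
#'   used when corrupting the prior or planting decoys in the genome
#'   scaffold.
#' @param n_perturb Number of TFs knocked out in the KO condition.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_tf = 20, n_gene = 400, n_sample_wt = 300,
                       n_sample_ko = 300, edges_per_gene = 3,
                       weight_scale = 1,
                       weight_model = c("signed_uniform", "unit"),
                       activation_prob = 0.8,
                       activity_model = c("gaussian", "lognormal"),
                       noise_sd = 0.25,
                       count_model = c("none", "poisson", "negbin"),
                       nb_dispersion = 10, prior_fpr = 0.02,
                       prior_fnr = 0.2, n_perturb = 1) {
  weight_model <- match.arg(weight_model)
  activity_model <- match.arg(activity_model)
  count_model <- match.arg(count_model)
  if (n_tf < 2) gn_value_error("n_tf must be >= 2")
  if (edges_per_gene < 1 || edges_per_gene > n_tf)
    gn_value_error("edges_per_gene must lie in [1, n_tf]")
  stopifnot(n_gene >= 1, n_sample_wt >= 1, n_sample_ko >= 1,
            weight_scale > 0, noise_sd >= 0, nb_dispersion > 0,
            prior_fpr >= 0, prior_fpr < 1, prior_fnr >= 0, prior_fnr < 1,
            activation_prob >= 0, activation_prob <= 1,
            n_perturb >= 1, n_perturb < n_tf)
  structure(as.list(environment()), class = "sim_params")
}

#' Generate a ground-truth regulatory system
#'
#' Draws a sparse signed TF-to-gene network with exactly
#' `edges_per_gene` regulators per gene, wild-type and knockout activity
#' matrices (the KO condition zeroes the perturbed TFs' columns), and the
#' uncorrupted binary prior (the support of the true network). The prior is
#' checked for full row rank (TF identifiability); a rank-deficient draw is
#' regenerated from a derived sub-seed.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @return A `truth_bundle` list: `w_true` ([network_matrix()] with
#'   confidence 1 on the support), `a_wt`, `a_ko` ([activity_matrix()]),
#'   `prior_true` ([prior_matrix()]), `perturbed_tfs`, `params`, `seed`.
#' @export
generate_truth <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  tf_ids <- sprintf("TF%03d", seq_len(params$n_tf))
  gene_ids <- sprintf("G%04d", seq_len(params$n_gene))

  for (attempt in 0:99) {
    gn_set_seed(if (attempt == 0) seed else gn_subseed(seed, attempt))
    w <- matrix(0, params$n_tf, params$n_gene,
                dimnames = list(tf_ids, gene_ids))
    for (g in seq_len(params$n_gene)) {
      regs <- sample.int(params$n_tf, params$edges_per_gene)
      if (params$weight_model == "unit") {
        w[regs, g] <- 1
      } else {
        mag <- runif(params$edges_per_gene, 0.5, 1.5) * params$weight_scale
        sign <- ifelse(runif(params$edges_per_gene) < params$activation_prob,
                       1, -1)
        w[regs, g] <- mag * sign
      }
    }
    support <- 1 * (w != 0)
    if (qr(support)$rank == params$n_tf) break
    if (attempt == 99)
      gn_value_error("could not generate a full-rank prior in 100 attempts")
  }

  draw_act <- function(n, ids) {
    a <- switch(params$activity_model,
                gaussian = matrix(rnorm(n * params$n_tf), n, params$n_tf),
                lognormal = matrix(rlnorm(n * params$n_tf),
                                   n, params$n_tf))
    dimnames(a) <- list(ids, tf_ids)
    a
  }
  a_wt <- draw_act(params$n_sample_wt,
                   sprintf("WT%04d", seq_len(params$n_sample_wt)))
  a_ko <- draw_act(params$n_sample_ko,
                   sprintf("KO%04d", seq_len(params$n_sample_ko)))
  perturbed <- gn_sort(sample(tf_ids, params$n_perturb))
  a_ko[, perturbed] <- 0

  structure(list(
    w_true = network_matrix(w, support),
    a_wt = activity_matrix(a_wt), a_ko = activity_matrix(a_ko),
    prior_true = prior_matrix(support),
    perturbed_tfs = perturbed, scaffold = NULL,
    params = params, seed = as.integer(seed)), class = "truth_bundle")
}

#' Generate expression data from a truth bundle
#'
#' The latent matrix is `A_cond %*% W_true` plus elementwise Gaussian noise
#' of sd `noise_sd`. With `count_model = "none"` the latent matrix is
#' returned directly (layer `"lognorm"`); with `"poisson"`/`"negbin"`,
#' counts are drawn with mean `exp(pmin(latent, 10))` (log link, clipped at
#' 10 so means stay finite). Noise and count draws use sub-seeds derived
#' from the bundle seed, so equal bundles give identical matrices.
#'
#' @param bundle A [generate_truth()] result.
#' @param condition `"wt"` or `"ko"`.
#' @return An [expression_matrix()].
#' @export
generate_expression <- function(bundle, condition = c("wt", "ko")) {
  condition <- match.arg(condition)
  p <- bundle$params
  a <- unclass(if (condition == "wt") bundle$a_wt else bundle$a_ko)
  m <- a %*% bundle$w_true$weights
  gn_set_seed(gn_subseed(bundle$seed, if (condition == "wt") 1L else 2L))
  if (p$noise_sd > 0)
    m <- m + matrix(rnorm(length(m), sd = p$noise_sd), nrow(m), ncol(m))
  if (p$count_model == "none")
    return(expression_matrix(m, layer = "lognorm"))
  mu <- exp(pmin(m, 10))
  gn_set_seed(gn_subseed(bundle$seed, if (condition == "wt") 3L else 4L))
  counts <- switch(p$count_model,
                   poisson = rpois(length(mu), mu),
                   negbin = rnbinom(length(mu), mu = mu,
                                    size = p$nb_dispersion))
  counts <- matrix(as.numeric(counts), nrow(mu), ncol(mu),
                   dimnames = dimnames(mu))
  expression_matrix(counts, layer = "counts")
}

#' Corrupt a prior with false and missing edges
#'
#' Each true edge is dropped with probability `fnr`; each absent edge is
#' added with probability `fpr`. Deterministic under `seed`.
#'
#' @param p A [prior_matrix()].
#' @param fpr,fnr False-positive / false-negative rates in `[0, 1)`.
#' @param seed Integer seed.
#' @return A binary [prior_matrix()] (evidence dropped).
#' @export
corrupt_prior <- function(p, fpr, fnr, seed = 1) {
  stopifnot(inherits(p, "prior_matrix"),
            fpr >= 0, fpr < 1, fnr >= 0, fnr < 1)
  gn_set_seed(seed)
  v <- 1 * (p$values != 0)
  u <- matrix(runif(length(v)), nrow(v), ncol(v))
  out <- v
  out[v != 0 & u < fnr] <- 0
  out[v == 0 & u < fpr] <- 1
  dimnames(out) <- dimnames(v)
  prior_matrix(out)
}
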
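make_act <- function(n, p, seed = 1, ids = sprintf("TF%02d", seq_len(p))) {
  set.seed(seed)
  activity_matrix(matrix(rnorm(n * p), n, p,
                         dimnames = list(sprintf("s%03d", seq_len(n)), ids)))
}

test_that("preselection ranks by |correlation| with prior-first and lex ties", {
  a <- make_act(100, 5, seed = 2)
  y <- unclass(a)[, "TF03"]
  sel <- preselect_predictors(y, a)
  expect_identical(sel[1], "TF03")

  # exact tie: duplicate column under two names, lexicographically smaller first
  v <- unclass(a)[, 1:3]
  a2 <- activity_matrix(cbind(v, TFzz = v[, 1])[,
                          c("TF01", "TF02", "TF03", "TFzz")])
  y2 <- v[, 2]
  sel2 <- preselect_predictors(y2, a2, cfg = bbsr_config(n_preselect = 4))
  pos <- match(c("TF01", "TFzz"), sel2)
  expect_true(pos[1] < pos[2])

  # prior-supported TFs precede unsupported ones regardless of correlation
  prior_col <- c(TF01 = 0, TF02 = 0, TF03 = 0, TF04 = 1, TF05 = 0)
  sel3 <- preselect_predictors(y, a, prior_col)
  expect_identical(sel3[1], "TF04")

  # self-edge excluded; zero-variance response warns and returns empty
  a3 <- make_act(50, 3, ids = c("g1", "TFa", "TFb"))
  expect_false("g1" %in% preselect_predictors(unclass(a3)[, 2], a3,
                                              gene_id = "g1"))
  expect_warning(out <- preselect_predictors(rep(1, 100), a), "zero-variance")
  expect_identical(out, character())
})

test_that("score_subset matches closed forms and flags collinearity", {
  set.seed(3)
  z <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("TF", 1:4)))
  y <- 2 * z[, 1]
  s <- score_subset(y, z, 1)
  expect_lt(s$rss, 1e-20)
  expect_equal(unname(s$betas), 2, tolerance = 1e-10)

  # empty subset: null-model BIC
  y2 <- rnorm(50)
  s0 <- score_subset(y2, z, integer(0))
  expect_equal(s0$bic, 50 * log(sum((y2 - mean(y2))^2) / 50))
  expect_identical(s0$k, 0L)

  # collinear design falls back to ridge and is flagged
  zc <- cbind(z[, 1], z[, 1])
  colnames(zc) <- c("a", "b")
  sc <- score_subset(y2, zc, 1:2)
  expect_true(attr(sc, "ridge_used"))
  expect_true(is.finite(sc$bic))
})

test_that("bbsr_gene agrees with the exhaustive QR oracle on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    n <- 50
    p <- sample(3:8, 1)
    ids <- sprintf("TF%02d", seq_len(p))  # lexicographic order = column order
    z <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("s%03d", 1:n),
                                                    ids))
    k_true <- sample(0:min(3, p), 1)
    beta <- numeric(p)
    if (k_true > 0) beta[sample(p, k_true)] <- runif(k_true, 0.5, 2) *
        sample(c(-1, 1), k_true, replace = TRUE)
    y <- drop(z %*% beta) + rnorm(n, sd = 0.5)
    a <- activity_matrix(z)
    res <- bbsr_gene(y, a, cfg = bbsr_config(n_preselect = p))
    orac <- bbsr_oracle(y, z)
    expect_identical(sort(res$diagnostics$best_subset),
                     sort(ids[orac$best_subset]))
    expect_equal(unname(res$weights[ids]), orac$beta_avg, tolerance = 1e-8)
    expect_equal(unname(res$confidence[ids]), orac$conf, tolerance = 1e-8)
    expect_equal(res$diagnostics$best_bic, min(orac$bics), tolerance = 1e-8)
  }
})

test_that("score_subset BIC values match the oracle across all subsets", {
  set.seed(19)
  n <- 50
  z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("TF", 1:3)))
  y <- drop(z %*% c(1, -0.5, 0)) + rnorm(n, sd = 0.3)
  orac <- bbsr_oracle(y, z)
  subsets <- list(integer(0), 1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  for (i in seq_along(subsets))
    expect_equal(score_subset(y, z, subsets[[i]])$bic, orac$bics[i],
                 tolerance = 1e-8)
})

test_that("noiseless support recovery, noise rejection, and dominant-model limit", {
  set.seed(5)
  z <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(sprintf("s%03d", 1:200), sprintf("TF%02d", 1:5)))
  a <- activity_matrix(z)
  # noiseless y from 2 of 5 TFs: exact support, confidences ~ 1
  y <- drop(z %*% c(1.5, 0, -2, 0, 0))
  res <- bbsr_gene(y, a)
  expect_identical(res$diagnostics$best_subset, c("TF01", "TF03"))
  expect_true(all(res$confidence[c("TF01", "TF03")] > 1 - 1e-6))
  expect_true(all(res$confidence[c("TF02", "TF04", "TF05")] == 0))

  # pure noise: BIC keeps the empty model for the vast majority of seeds
  # (expected rate 0.88 on these seeds, frozen from an oracle run of the
  # exhaustive QR enumeration)
  empty <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    yn <- rnorm(200)
    length(bbsr_gene(yn, a)$diagnostics$best_subset) == 0
  }, TRUE)
  expect_equal(mean(empty), 0.88)

  # one dominant model (singleton enumeration, so every competitor is
  # dozens of BIC units away): averaged weights equal the best-model OLS
  # betas to machine precision
  y2 <- drop(z %*% c(3, 0, 0, 0, 0)) + rnorm(200, sd = 0.3)
  res2 <- bbsr_gene(y2, a, cfg = bbsr_config(n_preselect = 5,
                                             max_subset_size = 1))
  expect_identical(res2$diagnostics$best_subset, "TF01")
  s2 <- score_subset(y2, unclass(a), "TF01")
  expect_equal(res2$weights["TF01"], s2$betas, tolerance = 1e-8)
})

test_that("infer_network is gene-independent and recovers noiseless truth", {
  p <- sim_params(n_tf = 6, n_gene = 50, n_sample_wt = 80, n_sample_ko = 5,
                  noise_sd = 0)
  b <- generate_truth(p, seed = 31)
  x <- generate_expression(b, "wt")
  a <- activity_matrix(unclass(b$a_wt))
  net <- infer_network(x, a, b$prior_true,
                       cfg = bbsr_config(n_preselect = 6))
  expect_identical(unname(net$confidence > 0),
                   unname(b$w_true$weights != 0))
  # permuting gene order permutes columns only
  xp <- expression_matrix(unclass(x)[, rev(colnames(x))], "lognorm")
  netp <- infer_network(xp, a, b$prior_true,
                        cfg = bbsr_config(n_preselect = 6))
  expect_identical(netp$weights, net$weights[, rev(colnames(x))])
})

test_that("adding pure-noise TFs barely moves AUPR", {
  p <- sim_params(n_tf = 6, n_gene = 60, n_sample_wt = 80, n_sample_ko = 5)
  b <- generate_truth(p, seed = 37)
  x <- generate_expression(b, "wt")
  a <- activity_matrix(unclass(b$a_wt))
  truth <- b$w_true$weights != 0
  net <- infer_network(x, a, b$prior_true)
  base_aupr <- average_precision(as.numeric(net$confidence),
                                 as.logical(truth))
  set.seed(41)
  noise <- matrix(rnorm(nrow(a) * 3), nrow(a), 3,
                  dimnames = list(rownames(a), paste0("ZZnoise", 1:3)))
  a2 <- activity_matrix(cbind(unclass(a), noise))
  net2 <- infer_network(x, a2, b$prior_true)
  aupr2 <- average_precision(as.numeric(net2$confidence[rownames(truth), ]),
                             as.logical(truth))
  expect_gt(aupr2, base_aupr - 0.05)
})

test_that("TF degree summary filters, ranks, and handles empty networks", {
  w <- matrix(0, 2, 5, dimnames = list(c("TF1", "TF2"), paste0("g", 1:5)))
  cf <- w
  cf["TF1", 1:4] <- c(0.9, 0.8, 0.7, 0.6)
  cf["TF2", 1] <- 0.95
  w[cf > 0] <- 1
  net <- network_matrix(w, cf)
  deg <- summarize_tf_degrees(net, min_conf = 0, min_targets = 4)
  expect_identical(deg$tf, "TF1")
  expect_identical(deg$n_targets, 4L)
  deg1 <- summarize_tf_degrees(net, min_conf = 0, min_targets = 1)
  expect_identical(deg1$tf, c("TF1", "TF2"))
  # raising min_conf prunes edges
  expect_identical(summarize_tf_degrees(net, min_conf = 0.65,
                                        min_targets = 4)$tf, character(0))
  empty <- network_matrix(w * 0, cf * 0)
  expect_identical(nrow(summarize_tf_degrees(empty, 0, 1)), 0L)
})

test_that("average precision matches hand-computed rankings", {
  # perfect ranking
  expect_equal(average_precision(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  # one inversion: hits at ranks 1 and 3 -> AP = (1 + 2/3)/2
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               (1 + 2 / 3) / 2)
  # all-tied scores collapse to a single block: AP = prevalence
  expect_equal(average_precision(rep(0.5, 4), c(1, 0, 1, 0)), 0.5)
  expect_error(average_precision(1:3, c(0, 0, 0)),
               class = "gremnet_value_error")
})
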
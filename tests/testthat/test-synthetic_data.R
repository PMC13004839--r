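small_params <- function(...) {
  args <- list(n_tf = 6, n_gene = 60, n_sample_wt = 50, n_sample_ko = 50,
               edges_per_gene = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

test_that("generate_truth enforces structure and determinism", {
  p <- small_params()
  b1 <- generate_truth(p, seed = 7)
  b2 <- generate_truth(p, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(colSums(b1$w_true$weights != 0) == 2))
  # KO zeroes exactly the perturbed TF columns
  expect_true(all(unclass(b1$a_ko)[, b1$perturbed_tfs] == 0))
  live <- setdiff(colnames(b1$a_ko), b1$perturbed_tfs)
  expect_true(all(colSums(unclass(b1$a_ko)[, live] != 0) > 0))
  # prior is the support of the true network, full row rank
  expect_identical(unname(b1$prior_true$values),
                   unname(1 * (b1$w_true$weights != 0)))
  expect_identical(qr(b1$prior_true$values)$rank, as.integer(p$n_tf))
  expect_error(sim_params(n_tf = 3, edges_per_gene = 5),
               class = "gremnet_value_error")
})

test_that("generated expression follows the stated observation model", {
  b0 <- generate_truth(small_params(noise_sd = 0), seed = 3)
  x0 <- generate_expression(b0, "wt")
  expect_equal(unname(unclass(x0)),
               unname(unclass(b0$a_wt) %*% b0$w_true$weights),
               ignore_attr = TRUE)

  bn <- generate_truth(small_params(noise_sd = 0.1, n_gene = 300), seed = 3)
  xn <- generate_expression(bn, "wt")
  resid <- unclass(xn) - unclass(bn$a_wt) %*% bn$w_true$weights
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.1) / 0.1, 0.2)

  # Poisson link: empirical variance tracks the mean at high mean
  bp <- generate_truth(small_params(noise_sd = 0, count_model = "poisson",
                                    weight_model = "unit",
                                    n_sample_wt = 2000), seed = 5)
  # unit weights, 2 regulators: latent is a sum of 2 activities
  xp <- generate_expression(bp, "wt")
  expect_identical(attr(xp, "layer"), "counts")
  lat <- unclass(bp$a_wt) %*% bp$w_true$weights
  mu <- exp(pmin(lat, 10))
  high <- which(mu > 50)
  expect_lt(abs(mean(unclass(xp)[high] / mu[high]) - 1), 0.1)
  expect_lt(abs(var(unclass(xp)[high] - mu[high]) /
                  mean(mu[high]) - 1), 0.2)
})

test_that("corrupt_prior identity, rates, and determinism", {
  b <- generate_truth(small_params(), seed = 9)
  expect_identical(corrupt_prior(b$prior_true, 0, 0, seed = 1)$values,
                   b$prior_true$values)
  # expected added-edge count ~ fpr * #absent over repeated seeds
  n_absent <- sum(b$prior_true$values == 0)
  added <- vapply(1:200, function(s) {
    cp <- corrupt_prior(b$prior_true, 0.05, 0, seed = s)
    sum(cp$values != 0) - sum(b$prior_true$values != 0)
  }, 0)
  expected <- 0.05 * n_absent
  se <- sqrt(0.05 * 0.95 * n_absent / 200)
  expect_lt(abs(mean(added) - expected), 4 * se)
  expect_identical(corrupt_prior(b$prior_true, 0.3, 0.3, seed = 42)$values,
                   corrupt_prior(b$prior_true, 0.3, 0.3, seed = 42)$values)
})

test_that("scaffold honours window constraints and closure to the true prior", {
  p <- small_params(prior_fpr = 0, prior_fnr = 0)
  b <- generate_truth(p, seed = 13)
  sc <- generate_scaffold(b, window_bp = 20000, seed = 2,
                          with_sequences = TRUE)
  # every planted peak's midpoint within the window of its gene's TSS
  mid <- (sc$peaks$start + sc$peaks$end) %/% 2
  tss <- sc$genes$tss[match(sc$planted$gene, sc$genes$gene_id)]
  expect_true(all(abs(tss - mid) <= 20000))
  # hits inside peaks
  expect_true(all(sc$motif_hits$start >= 0 &
                    sc$motif_hits$stop <= sc$peaks$end - sc$peaks$start))
  # closure: rebuilt prior equals the true support exactly
  pr <- scaffold_prior(sc)
  expect_identical(
    unname(pr$values[b$prior_true$tf_ids, b$prior_true$gene_ids] != 0),
    unname(b$prior_true$values != 0))
  # embedded sites score at the motif maximum
  for (i in head(seq_len(nrow(sc$motif_hits)), 10)) {
    h <- sc$motif_hits[i, ]
    m <- sc$motifs[[h$motif_id]]
    hits <- scan_pwm(sc$sequences[[h$sequence_name]], m,
                     score = pwm_max_score(m) - 1e-9)
    expect_true(h$start %in% hits$start)
  }
  # layout error when the chromosome cannot hold the genes
  expect_error(generate_scaffold(b, window_bp = 20000, seed = 2,
                                 chrom_length = 1000),
               class = "gremnet_layout_error")
})

test_that("fixture files are written and read back consistently", {
  p <- small_params(prior_fpr = 0.05, prior_fnr = 0.1)
  b <- generate_truth(p, seed = 21)
  sc <- generate_scaffold(b, window_bp = 10000, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixture_set(b, sc, dir)
  x <- read_counts(paths$counts_wt, layer = "lognorm")
  expect_equal(unclass(x), unclass(generate_expression(b, "wt")),
               tolerance = 1e-10)
  pk <- read_bed_peaks(paths$peaks)
  expect_identical(pk$peak_id, sc$peaks$peak_id)
  pr <- read_prior(paths$prior_true, tf_ids = b$prior_true$tf_ids,
                   gene_ids = b$prior_true$gene_ids)
  expect_identical(unname(pr$values != 0), unname(b$prior_true$values != 0))
  a <- read_activities(paths$tfa_wt)
  expect_equal(unclass(a), unclass(b$a_wt), tolerance = 1e-10,
               ignore_attr = TRUE)
})
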
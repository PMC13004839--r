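test_that("simple_differential: fold changes, BH step-up, and power", {
  set.seed(6)
  xa <- make_em(matrix(rnorm(50, 5), 10, 5))
  # identical groups -> zero log2fc
  d0 <- simple_differential(xa, xa)
  expect_true(all(d0$log2fc == 0))

  # BH on (0.01, 0.02, 0.03, 0.04) -> all 0.04 (hand-applied step-up)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  # Welch p-values agree with stats::t.test
  xb <- make_em(matrix(rnorm(50, 5.2), 10, 5))
  d <- simple_differential(xa, xb)
  for (g in colnames(xa)) {
    ref <- t.test(unclass(xa)[, g], unclass(xb)[, g])
    expect_equal(d$pvalue[d$feature_id == g], ref$p.value, tolerance = 1e-10)
  }

  # strong shift with tiny variance is detected
  set.seed(7)
  xs <- make_em(matrix(rnorm(200, sd = 0.05), 10, 20) + 1)
  ds <- simple_differential(xs, make_em(matrix(rnorm(200, sd = 0.05), 10, 20)))
  expect_true(all(ds$padj < 0.05))

  # zero variance in both groups: p = 1, flagged
  xc <- make_em(matrix(3, 4, 2))
  xd <- make_em(matrix(5, 4, 2))
  dz <- simple_differential(xc, xd)
  expect_true(all(dz$pvalue == 1 & dz$flagged))
})

test_that("gene-level accessibility picks the best peak with fixed tie rules", {
  recs <- data.frame(feature_id = c("p1", "p2", "p3", "p4"),
                     log2fc = c(0.3, 0.8, 0.3, 0.5),
                     pvalue = c(0.1, 0.005, 0.02, 0.02),
                     padj = c(0.2, 0.01, 0.05, 0.05))
  assignment <- list(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gB",
                     p9 = character(0))
  out <- gene_level_accessibility(recs, assignment)
  expect_identical(out$gA$best_peak_id, "p2")     # min padj
  expect_identical(out$gB$best_peak_id, "p4")     # padj tie -> larger |lfc|
  # padj tie and |lfc| tie -> lexicographically smaller peak id
  recs2 <- data.frame(feature_id = c("pB", "pA"), log2fc = c(0.5, -0.5),
                      pvalue = c(0.01, 0.01), padj = c(0.02, 0.02))
  out2 <- gene_level_accessibility(recs2, list(pB = "g", pA = "g"))
  expect_identical(out2$g$best_peak_id, "pA")
  # gene with no peaks absent
  expect_false("gC" %in% names(out))
})

test_that("concordance classification matches the brute-force oracle", {
  t <- concordance_thresholds()
  set.seed(9)
  n <- 1000
  # random records with exact boundary values salted in
  lfc_pool <- c(rnorm(n - 8, sd = 0.5),
                0.25, -0.25, 0.1, -0.1, 0.2499, 0.2501, 0, 1)
  padj_pool <- c(runif(n - 6), 0.05, 0.05, 0.0499, 0.0501, NA, NA)
  rna <- data.frame(feature_id = sprintf("g%04d", 1:n),
                    log2fc = sample(lfc_pool),
                    pvalue = runif(n),
                    padj = sample(padj_pool))
  atac_lfc <- sample(lfc_pool)
  atac_padj <- sample(padj_pool)
  atac <- lapply(seq_len(n), function(i)
    list(log2fc = atac_lfc[i], pvalue = 0.5, padj = atac_padj[i],
         best_peak_id = sprintf("pk%04d", i)))
  names(atac) <- rna$feature_id
  got <- classify_concordance(rna, atac, t)
  for (i in seq_len(n)) {
    exp_i <- concordance_oracle_one(rna$log2fc[i], rna$padj[i],
                                    atac_lfc[i], atac_padj[i], t)
    expect_identical(c(got$rna_state[i], got$atac_state[i], got$label[i]),
                     exp_i)
  }
  # labels partition the gene set
  expect_identical(sum(table(got$label)), as.integer(n))
  # inclusive boundaries explicitly
  rna1 <- data.frame(feature_id = "g1", log2fc = 0.25, pvalue = 0.01,
                     padj = 0.05)
  atac1 <- list(g1 = list(log2fc = 0.1, pvalue = 0.01, padj = 0.05,
                          best_peak_id = "pk1"))
  expect_identical(classify_concordance(rna1, atac1, t)$label,
                   "concordant_up")
  # duplicate genes rejected
  expect_error(classify_concordance(rbind(rna1, rna1), atac1, t),
               class = "gremnet_consistency_error")
})

test_that("raising thresholds never promotes a gene to significance", {
  set.seed(10)
  rna <- data.frame(feature_id = sprintf("g%03d", 1:200),
                    log2fc = rnorm(200, sd = 0.5), pvalue = runif(200),
                    padj = runif(200))
  atac <- list()
  for (lfc in c(0.1, 0.25, 0.5, 1)) {
    lo <- classify_concordance(rna, atac, concordance_thresholds(rna_lfc = lfc))
    hi <- classify_concordance(rna, atac,
                               concordance_thresholds(rna_lfc = lfc * 2))
    promoted <- lo$rna_state == "ns" & hi$rna_state != "ns"
    expect_false(any(promoted))
  }
})

test_that("z-scoring standardises genes and flags constants", {
  x <- make_em(cbind(c(1, 2, 3), c(7, 7, 7)), genes = c("g1", "g2"))
  z <- zscore_matrix(x)
  expect_equal(unname(z[, "g1"]), c(-1, 0, 1))
  expect_true(all(z[, "g2"] == 0))
  expect_identical(attr(z, "flagged_genes"), "g2")
  set.seed(12)
  x2 <- make_em(matrix(rnorm(60), 10, 6))
  z2 <- zscore_matrix(x2)
  expect_equal(unname(colMeans(z2)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 2, sd)), rep(1, 6), tolerance = 1e-12)
})

test_that("knockouts under mean-shifting activities yield concordant calls", {
  # lognormal activities have positive mean, so zeroing a TF shifts its
  # targets' mean expression; a promoter-accessibility proxy built from
  # half the network weight must then move in the same direction
  p <- sim_params(n_tf = 6, n_gene = 80, n_sample_wt = 60, n_sample_ko = 60,
                  edges_per_gene = 2, activity_model = "lognormal")
  b <- generate_truth(p, seed = 55)
  rna <- simple_differential(generate_expression(b, "ko"),
                             generate_expression(b, "wt"))
  set.seed(56)
  acc <- lapply(list(wt = b$a_wt, ko = b$a_ko), function(a) {
    m <- unclass(a) %*% (0.5 * b$w_true$weights)
    expression_matrix(m + matrix(rnorm(length(m), sd = 0.25),
                                 nrow(m), ncol(m)), "lognorm")
  })
  atac_tab <- simple_differential(acc$ko, acc$wt)
  atac <- lapply(seq_len(nrow(atac_tab)), function(r)
    list(log2fc = atac_tab$log2fc[r], pvalue = atac_tab$pvalue[r],
         padj = atac_tab$padj[r], best_peak_id = atac_tab$feature_id[r]))
  names(atac) <- atac_tab$feature_id
  cls <- classify_concordance(rna, atac)
  sig <- cls$rna_state != "ns" | cls$atac_state != "ns"
  expect_gte(sum(sig), 5)
  conc <- cls$label %in% c("concordant_up", "concordant_down")
  expect_gte(sum(conc) / sum(sig), 0.5)
  # at least half the knocked-out TF's direct targets are called
  # concordant (per-gene variance scales with the same weights as the
  # knockout shift, so power is partial by construction), and every
  # concordant target moves against its edge sign: losing an activator
  # drops the gene, losing a repressor raises it
  w_ko <- b$w_true$weights[b$perturbed_tfs, ]
  targets <- colnames(b$w_true$weights)[w_ko != 0]
  expect_gte(mean(targets %in% cls$gene_id[conc]), 0.5)
  conc_targets <- intersect(cls$gene_id[conc], targets)
  expected_label <- ifelse(w_ko[conc_targets] > 0,
                           "concordant_down", "concordant_up")
  expect_identical(cls$label[match(conc_targets, cls$gene_id)],
                   unname(expected_label))
})
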
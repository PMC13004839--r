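# Independent oracles and small fixture builders shared across tests.

# quick expression-matrix builder with auto ids
make_em <- function(values, layer = "lognorm", samples = NULL, genes = NULL) {
  values <- as.matrix(values)
  rownames(values) <- samples %||% sprintf("s%02d", seq_len(nrow(values)))
  colnames(values) <- genes %||% sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, layer = layer)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive best-subset oracle, independent of the package's C++ path:
# QR-based OLS via lm.fit per subset, subsets enumerated size-then-lex via
# utils::combn. Mirrors the documented scoring semantics exactly.
bbsr_oracle <- function(y, z, prior_flag = integer(ncol(z)), bonus = 0,
                        max_size = ncol(z)) {
  n <- length(y); p <- ncol(z)
  yc <- y - mean(y)
  zc <- scale(z, center = TRUE, scale = FALSE)
  syy <- sum(yc^2)
  floor_ <- max(syy * 1e-12, 1e-300)
  subsets <- list(integer(0))
  for (k in seq_len(min(max_size, p))) {
    cmb <- utils::combn(p, k)
    subsets <- c(subsets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  fits <- lapply(subsets, function(s) {
    k <- length(s)
    if (k == 0) {
      rss <- syy; beta <- numeric(0)
    } else {
      fit <- lm.fit(zc[, s, drop = FALSE], yc)
      beta <- fit$coefficients
      rss <- sum(fit$residuals^2)
    }
    bic <- n * log(max(rss, floor_) / n) + k * log(n) -
      bonus * sum(prior_flag[s] != 0)
    list(rss = rss, bic = bic, beta = beta)
  })
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- which.min(bics)  # first minimum = smaller/lex-earlier subset
  w <- exp(-0.5 * (bics - bics[best]))
  w <- w / sum(w)
  beta_avg <- numeric(p)
  for (i in seq_along(subsets))
    beta_avg[subsets[[i]]] <- beta_avg[subsets[[i]]] + w[i] * fits[[i]]$beta
  conf <- numeric(p)
  for (t in subsets[[best]]) {
    excl <- which(vapply(subsets, function(s) !(t %in% s), TRUE))
    be <- excl[which.min(bics[excl])]
    conf[t] <- max(0, min(1, 1 - fits[[best]]$rss / fits[[be]]$rss))
  }
  list(best_subset = subsets[[best]], bics = bics, beta_avg = beta_avg,
       conf = conf, best_rss = fits[[best]]$rss)
}

# Brute-force concordance state/label rules, coded independently of the
# package (plain nested conditionals over one record).
concordance_oracle_one <- function(r_lfc, r_padj, a_lfc, a_padj, t) {
  state <- function(lfc, padj, alpha, cut) {
    if (is.na(padj)) return("ns")
    if (padj > alpha) return("ns")
    if (!is.na(lfc) && lfc >= cut) return("up")
    if (!is.na(lfc) && lfc <= -cut) return("down")
    "ns"
  }
  rs <- state(r_lfc, r_padj, t$rna_alpha, t$rna_lfc)
  as <- state(a_lfc, a_padj, t$atac_alpha, t$atac_lfc)
  lab <- if (rs == "up" && as == "up") "concordant_up"
  else if (rs == "down" && as == "down") "concordant_down"
  else if (rs %in% c("up", "down") && as %in% c("up", "down")) "discordant"
  else if (rs %in% c("up", "down")) "expression_only"
  else if (as %in% c("up", "down")) "accessibility_only"
  else "neither"
  c(rs, as, lab)
}

# exhaustive PWM tail distribution by enumerating all 4^L sequences on the
# same integer score bins the DP uses
pwm_tail_oracle <- function(pm, bins) {
  k <- round(gremnet:::pwm_log_odds(pm) / 1e-3)
  L <- nrow(k)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  total <- numeric(nrow(grid))
  prob <- rep(1, nrow(grid))
  for (i in seq_len(L)) {
    total <- total + k[i, grid[, i]]
    prob <- prob * pm$background[grid[, i]]
  }
  vapply(bins, function(t) sum(prob[total >= t]), 0)
}
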
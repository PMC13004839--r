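// Exhaustive best-subset regression for one gene: all subsets of the
// preselected candidate TFs up to max_size are scored by BIC (computed
// from precomputed Gram matrices), the best model is chosen with fixed
// tie-breaking (smaller subset first, then lexicographic enumeration
// order), coefficients are model-averaged with exponential BIC weights,
// and per-TF confidences are 1 - rss_best / rss_best_without_tf.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Enumerate all index subsets of {0..p-1} with size <= max_size, ordered by
// size then lexicographically, so that strict improvement comparisons give
// the smaller/lexicographically-earlier subset on ties.
static void enumerate_subsets(int p, int max_size,
                              std::vector<std::vector<unsigned>>& out) {
  out.clear();
  out.push_back({});  // empty model
  for (int k = 1; k <= max_size && k <= p; ++k) {
    std::vector<unsigned> comb(k);
    for (int i = 0; i < k; ++i) comb[i] = i;
    while (true) {
      out.push_back(comb);
      int i = k - 1;
      while (i >= 0 && comb[i] == (unsigned)(p - k + i)) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
  }
}

// [[Rcpp::export(name = ".bbsr_enumerate")]]
List bbsr_enumerate(const arma::mat& Z, const arma::vec& y,
                    const arma::ivec& prior_flag, double bonus,
                    int max_size) {
  const int n = Z.n_rows, p = Z.n_cols;
  const arma::mat G = Z.t() * Z;
  const arma::vec b = Z.t() * y;
  const double syy = arma::dot(y, y);
  // BIC floor on rss: near-exact fits are compared by the penalty term
  // rather than by the log of numerical noise
  const double rss_floor = std::max(syy * 1e-12, 1e-300);

  std::vector<std::vector<unsigned>> subsets;
  enumerate_subsets(p, std::min(max_size, p), subsets);
  const size_t m = subsets.size();

  std::vector<double> eff_bic(m), rss_all(m);
  std::vector<arma::vec> betas(m);
  bool ridge_used = false;

  for (size_t s = 0; s < m; ++s) {
    const std::vector<unsigned>& sub = subsets[s];
    const int k = (int)sub.size();
    double rss;
    arma::vec beta;
    if (k == 0) {
      rss = syy;
    } else {
      arma::uvec idx(k);
      for (int i = 0; i < k; ++i) idx[i] = sub[i];
      arma::mat Gs = G.submat(idx, idx);
      arma::vec bs = b.elem(idx);
      bool ok = arma::solve(beta, Gs, bs,
                            arma::solve_opts::likely_sympd +
                            arma::solve_opts::no_approx);
      if (!ok || !beta.is_finite()) {
        // collinear candidates: ridge fallback, flagged
        ok = arma::solve(beta, Gs + 1e-8 * arma::eye(k, k), bs);
        ridge_used = true;
        if (!ok) stop("bbsr: singular design not recoverable by ridge");
      }
      rss = syy - arma::dot(bs, beta);
      if (rss < 0) rss = 0;
    }
    rss_all[s] = rss;
    betas[s] = beta;
    double bic = n * std::log(std::max(rss, rss_floor) / n) +
                 k * std::log((double)n);
    int n_prior = 0;
    for (unsigned j : sub) if (prior_flag[j] != 0) ++n_prior;
    eff_bic[s] = bic - bonus * n_prior;
  }

  // best model (strict improvement keeps the first = smallest/lex-earliest)
  size_t best = 0;
  for (size_t s = 1; s < m; ++s)
    if (eff_bic[s] < eff_bic[best]) best = s;

  // per-candidate best model excluding that candidate
  std::vector<double> excl_bic(p, R_PosInf), excl_rss(p, R_PosInf);
  for (size_t s = 0; s < m; ++s) {
    std::vector<bool> in(p, false);
    for (unsigned j : subsets[s]) in[j] = true;
    for (int t = 0; t < p; ++t)
      if (!in[t] && eff_bic[s] < excl_bic[t]) {
        excl_bic[t] = eff_bic[s];
        excl_rss[t] = rss_all[s];
      }
  }

  // model-averaged coefficients, weights exp(-0.5 * (bic - bic_min))
  const double bic_min = eff_bic[best];
  arma::vec beta_avg(p, arma::fill::zeros);
  double wsum = 0;
  for (size_t s = 0; s < m; ++s) {
    double w = std::exp(-0.5 * (eff_bic[s] - bic_min));
    wsum += w;
    const std::vector<unsigned>& sub = subsets[s];
    for (size_t i = 0; i < sub.size(); ++i)
      beta_avg[sub[i]] += w * betas[s][i];
  }
  beta_avg /= wsum;

  // confidences: only best-model members are nonzero
  arma::vec conf(p, arma::fill::zeros);
  arma::vec beta_best(p, arma::fill::zeros);
  const std::vector<unsigned>& bs_sub = subsets[best];
  for (size_t i = 0; i < bs_sub.size(); ++i) {
    unsigned t = bs_sub[i];
    beta_best[t] = betas[best][i];
    double denom = excl_rss[t];
    double c = (denom > 0 && std::isfinite(denom))
                 ? 1.0 - rss_all[best] / denom : 0.0;
    conf[t] = std::max(0.0, std::min(1.0, c));
  }

  IntegerVector best_idx(bs_sub.size());
  for (size_t i = 0; i < bs_sub.size(); ++i) best_idx[i] = bs_sub[i] + 1;

  return List::create(
      _["best_subset"] = best_idx,
      _["best_bic"] = eff_bic[best],
      _["best_rss"] = rss_all[best],
      _["beta_best"] = beta_best,
      _["beta_avg"] = beta_avg,
      _["confidence"] = conf,
      _["ridge_used"] = ridge_used,
      _["n_subsets"] = (int)m);
}
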
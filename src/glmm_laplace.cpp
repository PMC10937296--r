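#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Binomial log-likelihood on the probability scale; `with_const` adds the
// log binomial coefficient so log-likelihoods are comparable with glm/glmer.
static double binom_loglik(const arma::vec& m, const arma::vec& tot,
                           const arma::vec& mu, bool with_const) {
  double ll = 0.0;
  for (arma::uword i = 0; i < m.n_elem; ++i) {
    double p = mu[i];
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    ll += m[i] * std::log(p) + (tot[i] - m[i]) * std::log1p(-p);
    if (with_const)
      ll += std::lgamma(tot[i] + 1.0) - std::lgamma(m[i] + 1.0) -
            std::lgamma(tot[i] - m[i] + 1.0);
  }
  return ll;
}

// Laplace-approximated marginal log-likelihood of a binomial logit mixed
// model with independent random intercepts, at fixed variance parameters.
//
// theta holds log standard deviations, one per grouping factor; Z is the
// 0/1 incidence matrix of all factor levels (facsize[i] columns for factor
// i, in order). Fixed effects are profiled out: the inner loop is a
// penalized IRLS to the joint (beta, u) mode on the spherical scale
// u = b / sigma, and the Laplace correction uses the u-block of the
// penalized information, matching the standard nAGQ = 1 convention.
//
// Returns the Laplace log-likelihood (including binomial constants) and,
// when `full`, the profiled beta, spherical modes u, vcov of beta (Schur
// complement at the mode), fitted probabilities and convergence flags.
// [[Rcpp::export]]
List glmm_laplace_eval(const arma::vec& m, const arma::vec& tot,
                       const arma::mat& X, const arma::mat& Z,
                       const arma::uvec& facsize, const arma::vec& theta,
                       bool full) {
  const arma::uword n = m.n_elem, p = X.n_cols, q = Z.n_cols;

  arma::mat M(n, p + q);
  M.cols(0, p - 1) = X;
  if (q > 0) {
    arma::vec sig(q);
    arma::uword off = 0;
    for (arma::uword f = 0; f < facsize.n_elem; ++f) {
      double s = std::exp(theta[f]);
      for (arma::uword j = 0; j < facsize[f]; ++j) sig[off + j] = s;
      off += facsize[f];
    }
    M.cols(p, p + q - 1) = Z.each_row() % sig.t();
  }

  // empirical-logit start
  arma::vec eta = arma::log((m + 0.5) / (tot - m + 0.5));
  arma::vec coef(p + q, arma::fill::zeros);
  double pdev = R_PosInf;
  bool ok = false;

  arma::vec mu, w;
  for (int it = 0; it < 200; ++it) {
    mu = 1.0 / (1.0 + arma::exp(-eta));
    w = tot % mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec zw = eta + (m - tot % mu) / w;

    arma::mat H = M.t() * (M.each_col() % w);
    for (arma::uword j = p; j < p + q; ++j) H(j, j) += 1.0;
    arma::vec rhs = M.t() * (w % zw);
    arma::vec prop;
    if (!arma::solve(prop, H, rhs, arma::solve_opts::likely_sympd))
      return List::create(_["loglik"] = NA_REAL, _["ok"] = false);

    // step-halving on the penalized deviance
    double step = 1.0, newpdev = R_PosInf;
    arma::vec cand = prop;
    for (int h = 0; h < 30; ++h) {
      cand = (it == 0) ? prop : coef + step * (prop - coef);
      arma::vec muc = 1.0 / (1.0 + arma::exp(-(M * cand)));
      double dev = -2.0 * binom_loglik(m, tot, muc, false);
      double pen = (q > 0)
        ? arma::dot(cand.subvec(p, p + q - 1), cand.subvec(p, p + q - 1))
        : 0.0;
      newpdev = dev + pen;
      if (std::isfinite(newpdev) && (it == 0 || newpdev <= pdev + 1e-9)) break;
      step /= 2.0;
    }
    double old = pdev;
    coef = cand;
    eta = M * coef;
    pdev = newpdev;
    if (std::fabs(old - pdev) < 1e-10 * (std::fabs(pdev) + 1.0)) {
      ok = true;
      break;
    }
  }

  mu = 1.0 / (1.0 + arma::exp(-eta));
  w = tot % mu % (1.0 - mu);
  w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });

  double ll = binom_loglik(m, tot, mu, true);
  double upen = (q > 0)
    ? arma::dot(coef.subvec(p, p + q - 1), coef.subvec(p, p + q - 1))
    : 0.0;

  arma::mat Hfull = M.t() * (M.each_col() % w);
  for (arma::uword j = p; j < p + q; ++j) Hfull(j, j) += 1.0;

  double ldet = 0.0;
  if (q > 0) {
    double sign;
    arma::log_det(ldet, sign, arma::mat(Hfull.submat(p, p, p + q - 1, p + q - 1)));
  }
  double lap = ll - 0.5 * upen - 0.5 * ldet;

  if (!full) return List::create(_["loglik"] = lap, _["ok"] = ok);

  arma::mat Hinv;
  bool inv_ok = arma::inv_sympd(Hinv, Hfull);
  if (!inv_ok) arma::pinv(Hinv, Hfull);
  List out = List::create(
    _["loglik"] = lap, _["ok"] = ok,
    _["beta"] = NumericVector(coef.begin(), coef.begin() + p),
    _["u"] = (q > 0)
      ? NumericVector(coef.begin() + p, coef.begin() + p + q)
      : NumericVector(0),
    _["vcov_beta"] = wrap(arma::mat(Hinv.submat(0, 0, p - 1, p - 1))),
    _["fitted"] = wrap(mu),
    _["max_abs_eta"] = arma::abs(eta).max());
  return out;
}
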
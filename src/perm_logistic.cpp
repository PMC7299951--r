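// Fast iteratively-reweighted-least-squares logistic regression used by the
// permutation engine.  The R-level glm() fit remains the fit of record for
// reported coefficients; this backend exists so that 10^4-scale permutation
// loops stay tractable.  Both compute the same Wald statistic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Returns true on a converged, non-separated fit; beta/cov are outputs.
static bool irls_logistic(const mat& X, const vec& y, vec& beta, mat& cov) {
  const uword p = X.n_cols;
  beta.zeros(p);
  double dev_old = std::numeric_limits<double>::infinity();
  bool converged = false;
  vec eta(y.n_elem), mu(y.n_elem), w(y.n_elem), z(y.n_elem);
  for (int it = 0; it < 40; ++it) {
    eta = X * beta;
    mu = 1.0 / (1.0 + exp(-eta));
    w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    z = eta + (y - mu) / w;
    mat Xw = X.each_col() % w;
    mat XtWX = X.t() * Xw;
    vec XtWz = Xw.t() * z;
    bool ok = solve(beta, XtWX, XtWz, solve_opts::no_approx);
    if (!ok || !beta.is_finite()) return false;
    vec mu2 = 1.0 / (1.0 + exp(-(X * beta)));
    double dev = 0.0;
    for (uword i = 0; i < y.n_elem; ++i) {
      double m = std::min(std::max(mu2(i), 1e-12), 1.0 - 1e-12);
      dev -= 2.0 * (y(i) * std::log(m) + (1.0 - y(i)) * std::log(1.0 - m));
    }
    if (std::abs(dev - dev_old) < 1e-8 * (std::abs(dev) + 0.1)) {
      converged = true;
      break;
    }
    dev_old = dev;
  }
  if (!converged) return false;
  // |beta| this large on standardized inputs indicates (quasi-)separation
  if (abs(beta).max() > 30.0) return false;
  mu = 1.0 / (1.0 + exp(-(X * beta)));
  w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
  mat XtWX = X.t() * (X.each_col() % w);
  if (!inv_sympd(cov, XtWX)) return false;
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_logistic_wald(const arma::mat& X, const arma::vec& y) {
  vec beta;
  mat cov;
  bool ok = irls_logistic(X, y, beta, cov);
  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  }
  vec se = sqrt(cov.diag());
  vec zstat = beta / se;
  Rcpp::NumericVector p(beta.n_elem);
  for (uword j = 0; j < beta.n_elem; ++j) {
    p[j] = 2.0 * R::pnorm(-std::fabs(zstat(j)), 0.0, 1.0, 1, 0);
  }
  return Rcpp::List::create(
      Rcpp::Named("ok") = true,
      Rcpp::Named("beta") = beta,
      Rcpp::Named("se") = se,
      Rcpp::Named("p") = p);
}

// Permutation null of the Wald p-value for design column j (1-based).
// Group labels y are shuffled uniformly (Fisher-Yates on R's RNG stream, so
// set.seed() in R controls reproducibility); every subject keeps its own
// predictor and covariate row.  Fits that fail (non-convergence, separation)
// are recorded with p = 1.
// [[Rcpp::export]]
Rcpp::List cpp_perm_pvals(const arma::mat& X, const arma::vec& y, int j, int B) {
  const uword n = y.n_elem;
  const uword jj = (uword)(j - 1);
  if (jj >= X.n_cols) Rcpp::stop("predictor column out of range");
  if (B < 1) Rcpp::stop("B must be >= 1");
  Rcpp::NumericVector pvals(B);
  int n_fail = 0;
  vec yp = y, beta;
  mat cov;
  for (int b = 0; b < B; ++b) {
    yp = y;
    for (uword i = n - 1; i > 0; --i) {
      uword k = (uword)(unif_rand() * (double)(i + 1));
      if (k > i) k = i;
      std::swap(yp(i), yp(k));
    }
    if (irls_logistic(X, yp, beta, cov)) {
      double se = std::sqrt(cov(jj, jj));
      double zstat = beta(jj) / se;
      pvals[b] = 2.0 * R::pnorm(-std::fabs(zstat), 0.0, 1.0, 1, 0);
    } else {
      pvals[b] = 1.0;
      ++n_fail;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("p") = pvals,
      Rcpp::Named("n_fail") = n_fail);
}
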
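// REML criterion for the two-ratio linear mixed model
//   Cov(y) = sigma2_e * (I + gg * K + gw * diag(w))
// profiled over sigma2_e and the fixed effects.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double reml_ll(const vec& y, const mat& X, const mat& K,
                      const vec& w, double gg, double gw, double* s2_out) {
  const uword n = y.n_elem, p = X.n_cols;
  mat V = gg * K;
  V.diag() += 1.0 + gw * w;
  mat L;
  if (!chol(L, V, "lower")) return -datum::inf;
  vec ty = solve(trimatl(L), y);
  mat tX = solve(trimatl(L), X);
  mat XtX = tX.t() * tX;
  vec beta = solve(XtX, tX.t() * ty);
  vec resid = ty - tX * beta;
  double rss = dot(resid, resid);
  double s2 = rss / (n - p);
  if (s2_out) *s2_out = s2;
  double ldV = 2.0 * accu(log(L.diag()));
  double sign, ldX;
  log_det(ldX, sign, XtX);
  return -0.5 * ((n - p) * std::log(s2) + ldV + ldX);
}

// [[Rcpp::export(name = ".reml_one")]]
double reml_one(const arma::vec& y, const arma::mat& X, const arma::mat& K,
                const arma::vec& w, double gg, double gw) {
  return reml_ll(y, X, K, w, gg, gw, nullptr);
}

// [[Rcpp::export(name = ".reml_batch")]]
arma::vec reml_batch(const arma::vec& y, const arma::mat& X,
                     const arma::mat& K, const arma::vec& w,
                     const arma::mat& gamma_pairs) {
  vec out(gamma_pairs.n_rows);
  for (uword i = 0; i < gamma_pairs.n_rows; ++i)
    out(i) = reml_ll(y, X, K, w, gamma_pairs(i, 0), gamma_pairs(i, 1),
                     nullptr);
  return out;
}
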
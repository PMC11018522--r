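// Inner loops of the multivariate empirical-Bayes shrinkage model:
// per-test per-component multivariate normal log-likelihoods and mixture
// posterior summaries (mean, sd, local false sign rate).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log N(b; 0, Sigma) via Cholesky; returns -Inf on failure
static double dmvnorm_log(const vec& b, const mat& Sigma) {
  mat L;
  if (!chol(L, Sigma, "lower")) return -datum::inf;
  vec z = solve(trimatl(L), b);
  double ldet = 2.0 * accu(log(L.diag()));
  return -0.5 * (b.n_elem * std::log(2.0 * datum::pi) + ldet + dot(z, z));
}

// [[Rcpp::export(name = ".mash_loglik")]]
arma::mat mash_loglik(const arma::mat& Bhat, const arma::mat& Shat,
                      const arma::mat& V, const arma::cube& Ucube) {
  const uword T = Bhat.n_rows, R = Bhat.n_cols, K = Ucube.n_slices;
  mat L(T, K);
  for (uword t = 0; t < T; ++t) {
    vec s = Shat.row(t).t();
    mat W = V % (s * s.t());           // S V S, measurement covariance
    vec b = Bhat.row(t).t();
    for (uword k = 0; k < K; ++k) {
      mat Sigma = Ucube.slice(k) + W;
      Sigma.diag() += 1e-12;
      L(t, k) = dmvnorm_log(b, Sigma);
    }
  }
  (void)R;
  return L;
}

// Mixture posterior summaries. Component 0 of Ucube must be the null
// (all-zero) matrix. pi has length K (aligned to Ucube slices).
// [[Rcpp::export(name = ".mash_posterior")]]
Rcpp::List mash_posterior(const arma::mat& Bhat, const arma::mat& Shat,
                          const arma::mat& V, const arma::cube& Ucube,
                          const arma::vec& pi) {
  const uword T = Bhat.n_rows, R = Bhat.n_cols, K = Ucube.n_slices;
  mat post_mean(T, R, fill::zeros), post_sd(T, R, fill::zeros);
  mat lfsr(T, R, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec s = Shat.row(t).t();
    mat W = V % (s * s.t());
    vec b = Bhat.row(t).t();
    vec loglik(K);
    for (uword k = 0; k < K; ++k) {
      mat Sigma = Ucube.slice(k) + W;
      Sigma.diag() += 1e-12;
      loglik(k) = dmvnorm_log(b, Sigma);
    }
    vec lw = log(pi) + loglik;         // pi_k = 0 excludes component exactly
    double m = lw.max();
    vec w = exp(lw - m);
    w /= accu(w);
    vec mean_acc(R, fill::zeros), m2_acc(R, fill::zeros);
    vec p_neg(R, fill::zeros), p_zero(R, fill::zeros);
    mat Winv = inv_sympd(W + 1e-12 * eye(R, R));
    for (uword k = 0; k < K; ++k) {
      if (w(k) <= 0) continue;
      const mat& U = Ucube.slice(k);
      if (accu(abs(U)) == 0.0) {      // null component: point mass at zero
        p_zero += w(k) * ones(R);
        continue;
      }
      // posterior for b | bhat under prior N(0, U): Sigma1 = (U^-1+W^-1)^-1
      mat A = U * inv_sympd(U + W + 1e-12 * eye(R, R)); // U (U+W)^-1
      vec mu = A * b;
      mat Sigma1 = U - A * U;
      vec sd1 = sqrt(clamp(Sigma1.diag(), 0.0, datum::inf));
      mean_acc += w(k) * mu;
      m2_acc += w(k) * (square(mu) + Sigma1.diag());
      for (uword r = 0; r < R; ++r) {
        if (sd1(r) > 0)
          p_neg(r) += w(k) * normcdf(0.0, mu(r), sd1(r));
        else if (mu(r) < 0) p_neg(r) += w(k);
        else if (mu(r) == 0) p_zero(r) += w(k);
      }
    }
    post_mean.row(t) = mean_acc.t();
    post_sd.row(t) = sqrt(clamp(m2_acc - square(mean_acc), 0.0,
                                datum::inf)).t();
    for (uword r = 0; r < R; ++r) {
      double neg = p_neg(r), zero = p_zero(r);
      double pos = std::max(0.0, 1.0 - neg - zero);
      lfsr(t, r) = std::min(1.0, std::min(neg + zero, pos + zero));
    }
  }
  return Rcpp::List::create(Rcpp::Named("post_mean") = post_mean,
                            Rcpp::Named("post_sd") = post_sd,
                            Rcpp::Named("lfsr") = lfsr);
}
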
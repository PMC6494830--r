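// Conjugate Gibbs sampler for the Bayesian linear trend model:
//   y = X beta + eps,  beta_k ~ N(0, 1/prior_prec_k),  tau = 1/var(eps) ~ Gamma(a0, b0)
// Full conditionals: beta | tau ~ N(A^{-1} tau X'y, A^{-1}), A = tau X'X + Lambda;
//                    tau | beta ~ Gamma(a0 + n/2, b0 + SSR/2).
// Uses R's RNG so set.seed() on the R side controls each chain's stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
NumericMatrix gibbs_chain_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::vec& prior_prec,
                              double a0, double b0,
                              int n_iter, int burnin, int thin,
                              double tau_fixed, double tau_init) {
  const int p = X.n_cols;
  const int n = X.n_rows;
  const arma::mat XtX = X.t() * X;
  const arma::vec Xty = X.t() * y;
  const arma::mat Lambda = arma::diagmat(prior_prec);

  const bool sample_tau = tau_fixed <= 0.0;
  double tau = sample_tau ? tau_init : tau_fixed;

  const int n_save = (n_iter - burnin + thin - 1) / thin;
  NumericMatrix out(n_save, p + 1);

  arma::vec beta(p, arma::fill::zeros);
  int row = 0;
  for (int it = 0; it < n_iter; ++it) {
    // beta | tau
    arma::mat A = tau * XtX + Lambda;
    arma::mat L = arma::chol(A, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), tau * Xty));
    arma::vec z(p);
    for (int k = 0; k < p; ++k) z(k) = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), z);

    // tau | beta
    if (sample_tau) {
      arma::vec resid = y - X * beta;
      double ssr = arma::dot(resid, resid);
      tau = R::rgamma(a0 + 0.5 * n, 1.0 / (b0 + 0.5 * ssr));
    }

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      for (int k = 0; k < p; ++k) out(row, k) = beta(k);
      out(row, p) = tau;
      ++row;
    }
  }
  return out;
}
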
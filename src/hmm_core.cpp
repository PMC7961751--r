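// Scaled forward / forward-backward recursions for a Gaussian-emission HMM.
// Emission log-densities are computed in R (vectorised over frames) and
// passed in as a K x N matrix for all sequences concatenated; `lengths`
// gives the frame count of each sequence.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log p(X|theta) by the forward algorithm with per-step normalisation.
// logdens: K x T, init: K, trans: K x K (row-stochastic).
static double forward_one(const arma::mat& logdens, const arma::vec& init,
                          const arma::mat& trans) {
  const arma::uword K = logdens.n_rows, T = logdens.n_cols;
  arma::vec alpha(K);
  double loglik = 0.0;
  // per-column max keeps exp() in range even for extreme densities
  double m = logdens.col(0).max();
  alpha = init % arma::exp(logdens.col(0) - m);
  double c = arma::accu(alpha);
  loglik += std::log(c) + m;
  alpha /= c;
  for (arma::uword t = 1; t < T; ++t) {
    m = logdens.col(t).max();
    alpha = (trans.t() * alpha) % arma::exp(logdens.col(t) - m);
    c = arma::accu(alpha);
    loglik += std::log(c) + m;
    alpha /= c;
  }
  return loglik;
}

// [[Rcpp::export]]
double forward_loglik_cpp(const arma::mat& logdens, const arma::vec& init,
                          const arma::mat& trans) {
  return forward_one(logdens, init, trans);
}

// One E-step over all sequences. Returns the total log-likelihood, the
// posterior state occupancies gamma (K x N), the summed transition
// posteriors (K x K) and the summed initial-state posteriors (K).
// [[Rcpp::export]]
List forward_backward_cpp(const arma::mat& logdens, const arma::vec& init,
                          const arma::mat& trans,
                          const arma::ivec& lengths) {
  const arma::uword K = logdens.n_rows;
  const arma::uword S = lengths.n_elem;
  arma::mat gamma(K, logdens.n_cols, arma::fill::zeros);
  arma::mat xi_sum(K, K, arma::fill::zeros);
  arma::vec init_sum(K, arma::fill::zeros);
  double loglik = 0.0;

  arma::uword off = 0;
  for (arma::uword s = 0; s < S; ++s) {
    const arma::uword T = (arma::uword)lengths(s);
    arma::mat dens(K, T);   // scaled emission densities exp(logdens - colmax)
    arma::vec colmax(T);
    for (arma::uword t = 0; t < T; ++t) {
      colmax(t) = logdens.col(off + t).max();
      dens.col(t) = arma::exp(logdens.col(off + t) - colmax(t));
    }
    arma::mat alpha(K, T);
    arma::vec cvec(T);
    alpha.col(0) = init % dens.col(0);
    cvec(0) = arma::accu(alpha.col(0));
    alpha.col(0) /= cvec(0);
    for (arma::uword t = 1; t < T; ++t) {
      alpha.col(t) = (trans.t() * alpha.col(t - 1)) % dens.col(t);
      cvec(t) = arma::accu(alpha.col(t));
      alpha.col(t) /= cvec(t);
    }
    loglik += arma::accu(arma::log(cvec)) + arma::accu(colmax);

    arma::mat beta(K, T);
    beta.col(T - 1).ones();
    for (arma::uword t = T - 1; t > 0; --t) {
      beta.col(t - 1) = trans * (dens.col(t) % beta.col(t)) / cvec(t);
      // renormalisation by cvec keeps beta O(1); cancels in gamma/xi ratios
    }
    for (arma::uword t = 0; t < T; ++t) {
      arma::vec g = alpha.col(t) % beta.col(t);
      g /= arma::accu(g);
      gamma.col(off + t) = g;
    }
    for (arma::uword t = 0; t + 1 < T; ++t) {
      arma::mat xi = (alpha.col(t) * (dens.col(t + 1) % beta.col(t + 1)).t())
                     % trans / cvec(t + 1);
      xi /= arma::accu(xi);
      xi_sum += xi;
    }
    init_sum += gamma.col(off);
    off += T;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum, _["init_sum"] = init_sum);
}
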
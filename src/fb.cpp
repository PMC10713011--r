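#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Scaled forward-backward run independently over sessions.
//
// logB : T x K expected log observation densities.
// Ptil : K x K exp of expected log transition probabilities (rows need not
//        sum to 1 under the variational expectation).
// pitil: length-K exp of expected log initial probabilities.
// starts, ends: 1-based inclusive session bounds.
//
// The first time point of each session uses pitil, never Ptil; expected
// transition counts (xisum) aggregate within-session steps only. logz is the
// sum of log scaling constants, i.e. log of the normalizer of the subjective
// joint under the variational parameter expectations.
// [[Rcpp::export]]
List fb_sessions(const arma::mat& logB, const arma::mat& Ptil,
                 const arma::rowvec& pitil,
                 const arma::ivec& starts, const arma::ivec& ends) {
  const int T = logB.n_rows, K = logB.n_cols, S = starts.n_elem;
  arma::mat gamma(T, K, arma::fill::zeros);
  arma::mat xisum(K, K, arma::fill::zeros);
  arma::rowvec init_counts(K, arma::fill::zeros);
  double logz = 0.0;

  for (int s = 0; s < S; ++s) {
    const int a = starts[s] - 1, b = ends[s] - 1, L = b - a + 1;
    arma::mat Bs(L, K);
    double msum = 0.0;
    for (int t = 0; t < L; ++t) {
      const double mt = logB.row(a + t).max();
      Bs.row(t) = arma::exp(logB.row(a + t) - mt);
      msum += mt;
    }
    arma::mat alpha(L, K);
    arma::vec c(L);
    arma::rowvec at = pitil % Bs.row(0);
    c[0] = arma::accu(at);
    if (!(c[0] > 0.0) || !std::isfinite(c[0]))
      stop("forward scaling underflow in session %d", s + 1);
    alpha.row(0) = at / c[0];
    for (int t = 1; t < L; ++t) {
      at = (alpha.row(t - 1) * Ptil) % Bs.row(t);
      c[t] = arma::accu(at);
      if (!(c[t] > 0.0) || !std::isfinite(c[t]))
        stop("forward scaling underflow in session %d", s + 1);
      alpha.row(t) = at / c[t];
    }
    arma::rowvec beta(K, arma::fill::ones);
    gamma.row(b) = alpha.row(L - 1);
    for (int t = L - 2; t >= 0; --t) {
      const arma::rowvec bb = Bs.row(t + 1) % beta;
      xisum += (alpha.row(t).t() * bb) % Ptil / c[t + 1];
      beta = (Ptil * bb.t()).t() / c[t + 1];
      arma::rowvec g = alpha.row(t) % beta;
      gamma.row(a + t) = g / arma::accu(g);
    }
    init_counts += gamma.row(a);
    logz += arma::accu(arma::log(c)) + msum;
  }
  return List::create(_["gamma"] = gamma, _["xisum"] = xisum,
                      _["init_counts"] = init_counts, _["logz"] = logz);
}
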
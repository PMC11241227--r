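#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// NIPALS PLS1 with the optional per-wavelength residual standardization after
// each extracted factor (the Shenk-Westerhaus mPLS modification). X residuals
// and the y residual arrive already centered; deflation and rescaling are
// done in place. Returns the per-factor weights, X-loadings, y-loadings,
// residual-scaling vectors, calibration scores, and the number of factors
// actually extracted (rank permitting).
// [[Rcpp::export]]
Rcpp::List mpls_engine(arma::mat E, arma::vec f, int n_factors,
                       bool standardize) {
  const uword n = E.n_rows, p = E.n_cols;
  const int K = n_factors;
  mat W(p, K, fill::zeros), P(p, K, fill::zeros), D(p, K, fill::ones);
  mat S(n, K, fill::zeros);
  vec q(K, fill::zeros);
  int k_actual = 0;
  const double tol = 1e-12 * std::max(1.0, accu(square(E)));

  for (int k = 0; k < K; ++k) {
    vec w = E.t() * f;
    const double nw = norm(w);
    if (!std::isfinite(nw) || nw < 1e-14) break;
    w /= nw;
    vec t = E * w;
    const double t2 = dot(t, t);
    if (!std::isfinite(t2) || t2 < tol) break;
    const double qk = dot(t, f) / t2;
    vec pk = E.t() * t / t2;
    E -= t * pk.t();
    f -= qk * t;
    vec d(p, fill::ones);
    if (standardize) {
      // columns of E stay mean-zero under deflation, so the per-wavelength
      // SD is just the scaled column norm (n-1 denominator, as in R's sd)
      rowvec ss = sum(square(E), 0);
      for (uword j = 0; j < p; ++j) {
        const double sd = std::sqrt(std::max(ss(j), 0.0) / double(n - 1));
        d(j) = (sd < 1e-12) ? 1.0 : sd;
      }
      E.each_row() /= d.t();
    }
    W.col(k) = w;
    P.col(k) = pk;
    D.col(k) = d;
    S.col(k) = t;
    q(k) = qk;
    k_actual = k + 1;
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("P") = P, Rcpp::Named("q") = q,
      Rcpp::Named("Dsd") = D, Rcpp::Named("scores") = S,
      Rcpp::Named("k_actual") = k_actual);
}

// Factor-recursion prediction: returns the n x K matrix of predictions at
// every factor count 1..K for already-centered spectra.
// [[Rcpp::export]]
arma::mat mpls_predict_engine(arma::mat E, const arma::mat& W,
                              const arma::mat& P, const arma::vec& q,
                              const arma::mat& Dsd, double y_mean) {
  const uword n = E.n_rows;
  const uword K = W.n_cols;
  mat out(n, K);
  vec acc(n, fill::value(y_mean));
  for (uword k = 0; k < K; ++k) {
    vec t = E * W.col(k);
    acc += q(k) * t;
    out.col(k) = acc;
    if (k + 1 < K) {
      E -= t * P.col(k).t();
      E.each_row() /= Dsd.col(k).t();
    }
  }
  return out;
}
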
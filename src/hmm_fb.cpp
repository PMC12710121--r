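#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward pass for a scalar Gaussian-emission HMM.
// Returns the data log-likelihood, the per-sample state posteriors
// (gamma, T x K) and the summed pairwise transition posteriors (xi, K x K).
// Posteriors are normalised per time step, which is exact for any positive
// per-step scaling of alpha and beta.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector mu,
                          NumericVector sigma2, NumericVector pi0,
                          NumericMatrix A) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K);     // emission densities
  for (int j = 0; j < K; ++j) {
    const double s2 = sigma2[j];
    const double c = 1.0 / std::sqrt(2.0 * M_PI * s2);
    for (int t = 0; t < T; ++t) {
      const double d = x[t] - mu[j];
      double b = c * std::exp(-0.5 * d * d / s2);
      B(t, j) = (b > 1e-300) ? b : 1e-300;
    }
  }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector cscale(T);
  double ll = 0.0;

  // forward
  double tot = 0.0;
  for (int j = 0; j < K; ++j) { alpha(0, j) = pi0[j] * B(0, j); tot += alpha(0, j); }
  cscale[0] = tot;
  for (int j = 0; j < K; ++j) alpha(0, j) /= tot;
  ll += std::log(tot);
  for (int t = 1; t < T; ++t) {
    tot = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, j);
      alpha(t, j) = s * B(t, j);
      tot += alpha(t, j);
    }
    cscale[t] = tot;
    for (int j = 0; j < K; ++j) alpha(t, j) /= tot;
    ll += std::log(tot);
  }

  // backward (scaled by the forward constants)
  for (int j = 0; j < K; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / cscale[t + 1];
    }
  }

  // posteriors
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int j = 0; j < K; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); s += gamma(t, j); }
    for (int j = 0; j < K; ++j) gamma(t, j) /= s;
  }
  NumericMatrix xi(K, K);
  std::vector<double> tmp(K * K);
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        const double v = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j);
        tmp[i * K + j] = v;
        s += v;
      }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) xi(i, j) += tmp[i * K + j] / s;
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}
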
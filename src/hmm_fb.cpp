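#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for a hidden Markov chain.
// logB: n x K log observation densities; A: K x K transition matrix
// (rows sum to 1); pi: initial distribution.
// Returns posteriors gamma (n x K), summed two-slice marginals xiSum
// (K x K, the E-step sufficient statistic for A), and the log-likelihood.
// [[Rcpp::export]]
List forwardBackwardC(NumericMatrix logB, NumericMatrix A, NumericVector pi) {
  const int n = logB.nrow(), K = logB.ncol();
  NumericMatrix B(n, K), alpha(n, K), beta(n, K), gamma(n, K);
  std::vector<double> c(n), shift(n);
  for (int t = 0; t < n; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }
  // forward pass with per-step normalization
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }
  double ll = 0.0;
  for (int t = 0; t < n; ++t) ll += std::log(c[t]) + shift[t];
  // backward pass
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  NumericMatrix xi(K, K);
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
    for (int i = 0; i < K; ++i) {
      for (int j = 0; j < K; ++j) {
        xi(i, j) += alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];
      }
    }
  }
  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  return List::create(_["gamma"] = gamma, _["xiSum"] = xi, _["logLik"] = ll);
}
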
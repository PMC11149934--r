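#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All-pairs orthogonalized amplitude-envelope correlation.
// re, im: n x R real and imaginary parts of the analytic signals.
// For the direction i -> j, the zero-lag component of region j collinear
// with region i is removed (c = <x_i, x_j> / <x_i, x_i> on the real
// signals; the analytic signal is linear, so the corrected envelope is
// |A_j - c * A_i|), and the Pearson correlation between |A_i| and the
// corrected envelope is accumulated. Directions are averaged.
// stride: envelope sampling step for the correlation; envelopes of a
// band-limited signal are themselves band-limited to about the bandwidth,
// so sampling them well above twice that rate leaves the estimate
// unchanged (the orthogonalization coefficients use the full signals).
// [[Rcpp::export]]
List aecPairsC(NumericMatrix re, NumericMatrix im, int stride = 1) {
  const int n = re.nrow(), R = re.ncol();
  if (stride < 1) stride = 1;
  const int m = (n + stride - 1) / stride;
  NumericMatrix env(m, R);
  std::vector<double> mu(R), sdv(R);
  for (int j = 0; j < R; ++j) {
    double s = 0.0;
    for (int t = 0, k = 0; t < n; t += stride, ++k) {
      double e = std::sqrt(re(t, j) * re(t, j) + im(t, j) * im(t, j));
      env(k, j) = e;
      s += e;
    }
    mu[j] = s / m;
    double v = 0.0;
    for (int k = 0; k < m; ++k) {
      double d = env(k, j) - mu[j];
      v += d * d;
    }
    sdv[j] = std::sqrt(v / (m - 1));
  }
  // raw-signal Gram matrix (full resolution)
  NumericMatrix G(R, R);
  for (int i = 0; i < R; ++i) {
    for (int j = i; j < R; ++j) {
      double s = 0.0;
      for (int t = 0; t < n; ++t) s += re(t, i) * re(t, j);
      G(i, j) = s;
      G(j, i) = s;
    }
  }
  NumericMatrix A(R, R);
  int nDegenerate = 0;
  for (int i = 0; i < R; ++i) {
    for (int j = i + 1; j < R; ++j) {
      double rsum = 0.0;
      int nok = 0;
      for (int dir = 0; dir < 2; ++dir) {
        const int a = dir == 0 ? i : j;  // reference region
        const int b = dir == 0 ? j : i;  // orthogonalized region
        if (G(a, a) <= 0.0) { ++nDegenerate; continue; }
        const double c = G(a, b) / G(a, a);
        double s1 = 0.0, s2 = 0.0, sx = 0.0;
        for (int t = 0, k = 0; t < n; t += stride, ++k) {
          const double er = re(t, b) - c * re(t, a);
          const double ei = im(t, b) - c * im(t, a);
          const double e = std::sqrt(er * er + ei * ei);
          s1 += e;
          s2 += e * e;
          sx += e * env(k, a);
        }
        const double mm = s1 / m;
        const double v = (s2 - m * mm * mm) / (m - 1);
        // a residual envelope at floating-point noise level (pure leakage)
        // leaves the correlation undefined: convention 0
        const double vref = sdv[b] * sdv[b] + mu[b] * mu[b];
        if (v <= 1e-20 * vref || sdv[a] <= 1e-300) { ++nDegenerate; continue; }
        const double cov = (sx - m * mm * mu[a]) / (m - 1);
        rsum += cov / (std::sqrt(v) * sdv[a]);
        ++nok;
      }
      const double val = nok > 0 ? rsum / nok : 0.0;
      A(i, j) = val;
      A(j, i) = val;
    }
  }
  return List::create(_["A"] = A, _["nDegenerate"] = nDegenerate);
}
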
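#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Standard normal CDF. erfc keeps full accuracy in the lower tail, which
// matters for very small delta_alpha where bin edges sit many sigma out.
static inline double ncdf(double z) { return 0.5 * erfc(-z * M_SQRT1_2); }

// CDF of the splitting-ratio distribution: equal-weight mixture of
// Normal(alpha, da^2) and Normal(1 - alpha, da^2), truncated to [0, 1]
// and renormalized. Symmetric about 1/2, so its mean is exactly 1/2.
struct TruncMix {
  double a, s, lo, Z;
  TruncMix(double alpha, double da) : a(alpha), s(da) {
    lo = 0.5 * (ncdf((0.0 - a) / s) + ncdf((a - 1.0) / s));
    double hi = 0.5 * (ncdf((1.0 - a) / s) + ncdf(a / s));
    Z = hi - lo;
  }
  double cdf(double x) const {
    if (x <= 0.0) return 0.0;
    if (x >= 1.0) return 1.0;
    return (0.5 * (ncdf((x - a) / s) + ncdf((x - 1.0 + a) / s)) - lo) / Z;
  }
};

// Divided-component weights of the transfer kernel: entry (i, j) is the
// probability that a daughter of a parent at srcMid[j] lands in destination
// bin i. Exact integral of the daughter-intensity density (1/I') P(I/I')
// over each destination bin, i.e. a CDF difference at the bin-edge ratios.
// Columns sum to the in-range daughter mass (< 1 only if the destination
// range truncates the daughter distribution).
// [[Rcpp::export]]
NumericMatrix partition_weights(NumericVector destEdges, NumericVector srcMid,
                                double alpha, double dalpha) {
  int B = destEdges.size() - 1, S = srcMid.size();
  TruncMix m(alpha, dalpha);
  NumericMatrix W(B, S);
  for (int j = 0; j < S; ++j) {
    double ip = srcMid[j];
    double prev = m.cdf(destEdges[0] / ip);
    for (int i = 0; i < B; ++i) {
      double r = destEdges[i + 1] / ip;
      if (r >= 1.0) {           // daughters never exceed the parent intensity
        W(i, j) = 1.0 - prev;
        break;                  // remaining rows stay exactly zero
      }
      double cur = m.cdf(r);
      W(i, j) = cur - prev;
      prev = cur;
    }
  }
  return W;
}

// One forward application of the transfer operator without materializing
// the kernel matrix: out = K %*% counts with per-column renormalization
// (each parent accounted for exactly once). diagBin is the 1-based
// destination bin holding each source representative intensity (the
// undivided, Dirac-delta term).
// [[Rcpp::export]]
NumericVector forward_counts(NumericVector destEdges, NumericVector srcMid,
                             NumericVector counts, IntegerVector diagBin,
                             double alpha, double dalpha, double ft) {
  int B = destEdges.size() - 1, S = srcMid.size();
  TruncMix m(alpha, dalpha);
  NumericVector out(B);
  for (int j = 0; j < S; ++j) {
    double cj = counts[j];
    if (cj == 0.0) continue;
    double ip = srcMid[j];
    double f0 = m.cdf(destEdges[0] / ip);
    double f1 = m.cdf(destEdges[B] / ip);
    double nrm = ft * (f1 - f0) + (1.0 - ft);
    double scale = cj / nrm;
    if (ft > 0.0) {
      double prev = f0;
      for (int i = 0; i < B; ++i) {
        double r = destEdges[i + 1] / ip;
        if (r >= 1.0) {
          out[i] += ft * scale * (1.0 - prev);
          break;
        }
        double cur = m.cdf(r);
        out[i] += ft * scale * (cur - prev);
        prev = cur;
      }
    }
    out[diagBin[j] - 1] += (1.0 - ft) * scale;
  }
  return out;
}
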
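#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent pass for the non-negative sparse driver of the
// electrodermal decomposition.
//
// Model: y = H q + B l + e, with q >= 0 penalised by lambda * sum(q).
// H has one column per driver knot: the SCR kernel h starting at sample
// idx[j] (0-based), truncated at the end of the signal.  The residual
// r = y - H q - B l and the weights q are updated in place.
//
// Each call runs full sweeps interleaved with cheap active-set sweeps
// (only knots with q > 0) and returns after a full sweep whose largest
// update is below tol, or after max_sweeps sweeps.
//
// [[Rcpp::export]]
double cd_driver_pass(NumericVector r, NumericVector q, NumericVector h,
                      IntegerVector idx, NumericVector hh, double lambda,
                      int max_sweeps, double tol) {
  const int n = r.size(), m = q.size(), kl = h.size();
  double max_delta = 0.0;
  for (int s = 0; s < max_sweeps; ++s) {
    const bool full = (s % 4 == 0);
    max_delta = 0.0;
    for (int j = 0; j < m; ++j) {
      if (!full && q[j] == 0.0) continue;
      const int s0 = idx[j];
      const int len = std::min(kl, n - s0);
      if (len <= 0 || hh[j] <= 0) continue;
      double g = 0.0;
      const double *rp = &r[s0];
      for (int k = 0; k < len; ++k) g += h[k] * rp[k];
      double qn = q[j] + (g - lambda) / hh[j];
      if (qn < 0.0) qn = 0.0;
      const double d = qn - q[j];
      if (d != 0.0) {
        double *rw = &r[s0];
        for (int k = 0; k < len; ++k) rw[k] -= d * h[k];
        q[j] = qn;
        const double ad = d < 0 ? -d : d;
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (full && max_delta < tol) return max_delta;
  }
  return max_delta;
}

// Dense convolution of a sparse driver with the kernel: returns H q.
// [[Rcpp::export]]
NumericVector driver_convolve(NumericVector q, NumericVector h,
                              IntegerVector idx, int n) {
  const int m = q.size(), kl = h.size();
  NumericVector out(n);
  for (int j = 0; j < m; ++j) {
    if (q[j] == 0.0) continue;
    const int s0 = idx[j];
    const int len = std::min(kl, n - s0);
    for (int k = 0; k < len; ++k) out[s0 + k] += q[j] * h[k];
  }
  return out;
}

// Approximate entropy (embedding m, tolerance r, Chebyshev distance,
// self-matches included): ApEn = phi(m) - phi(m+1).
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2 || r <= 0) return NA_REAL;
  auto phi = [&](int mm) {
    const int nv = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nv; ++i) {
      int cnt = 0;
      for (int j = 0; j < nv; ++j) {
        double dmax = 0.0;
        for (int k = 0; k < mm; ++k) {
          double d = std::abs(x[i + k] - x[j + k]);
          if (d > dmax) dmax = d;
          if (dmax > r) break;
        }
        if (dmax <= r) ++cnt;
      }
      acc += std::log((double)cnt / nv);
    }
    return acc / nv;
  };
  return phi(m) - phi(m + 1);
}
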
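#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filter, zero initial state.
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 const double* x, double* y, R_xlen_t n) {
  int nz = (int)std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (size_t i = 0; i < b.size(); i++) bb[i] = b[i];
  for (size_t i = 0; i < a.size(); i++) aa[i] = a[i];
  if (nz == 6) {
    // register-resident specialization for the order-3 bandpass (7 taps)
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4], b5 = bb[5], b6 = bb[6];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4], a5 = aa[5], a6 = aa[6];
    double z0 = 0, z1 = 0, z2 = 0, z3 = 0, z4 = 0, z5 = 0;
    for (R_xlen_t i = 0; i < n; i++) {
      const double xi = x[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi + z4 - a4 * yi;
      z4 = b5 * xi + z5 - a5 * yi;
      z5 = b6 * xi - a6 * yi;
      y[i] = yi;
    }
    return;
  }
  std::vector<double> z(nz, 0.0);
  for (R_xlen_t i = 0; i < n; i++) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; j++) z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
}

// Single-pass IIR filter y = filter(b, a, x).
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  df2t(bv, av, REAL(x), REAL(y), n);
  return y;
}

// Zero-phase (forward-backward) IIR filter with edge-reflection padding.
// [[Rcpp::export]]
NumericVector iir_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  R_xlen_t n = x.size();
  int np = 3 * ((int)std::max(b.size(), a.size()) - 1);
  if (np > (int)n - 1) np = (int)n - 1;
  if (np < 0) np = 0;
  R_xlen_t m = n + 2 * np;
  std::vector<double> xp(m), tmp(m);
  // reflect about the end values: 2*x[0] - x[k]
  for (int i = 0; i < np; i++) xp[i] = 2.0 * x[0] - x[np - i];
  for (R_xlen_t i = 0; i < n; i++) xp[np + i] = x[i];
  for (int i = 0; i < np; i++) xp[np + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  df2t(bv, av, xp.data(), tmp.data(), m);
  std::reverse(tmp.begin(), tmp.end());
  df2t(bv, av, tmp.data(), xp.data(), m);
  std::reverse(xp.begin(), xp.end());
  NumericVector y(n);
  for (R_xlen_t i = 0; i < n; i++) y[i] = xp[np + i];
  return y;
}

static double median_inplace(std::vector<double>& v) {
  size_t n = v.size();
  size_t k = n / 2;
  std::nth_element(v.begin(), v.begin() + k, v.end());
  double hi = v[k];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + k - 1, v.begin() + k);
  return 0.5 * (v[k - 1] + hi);
}

// Unscaled median absolute deviation: median(|x - median(x)|).
// [[Rcpp::export]]
double mad_unscaled(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  double med = median_inplace(v);
  for (size_t i = 0; i < v.size(); i++) v[i] = std::fabs(x[i] - med);
  return median_inplace(v);
}

// Indices (1-based) of local minima strictly below `threshold`.
// A sample is a local minimum if x[i] <= x[i-1] and x[i] < x[i+1]
// (first sample of a flat trough wins; trace endpoints excluded).
// [[Rcpp::export]]
IntegerVector local_minima_below(NumericVector x, double threshold) {
  R_xlen_t n = x.size();
  std::vector<int> idx;
  for (R_xlen_t i = 1; i + 1 < n; i++) {
    if (x[i] < threshold && x[i] <= x[i - 1] && x[i] < x[i + 1]) {
      idx.push_back((int)(i + 1));
    }
  }
  return wrap(idx);
}
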
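#include <Rcpp.h>
using namespace Rcpp;

// One-pass IIR filter (direct form II transposed), zero initial state.
// b and a must be pre-padded to length ns + 1.
// Filters up to order MAXNS run through a fixed-bound loop the compiler can
// unroll and keep in registers; higher orders use the generic loop.
#define MAXNS 8
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x) {
  const size_t ns = b.size() - 1, n = x.size();
  if (ns <= MAXNS) {
    double bb[MAXNS + 1] = {0.0}, aa[MAXNS + 1] = {0.0}, z[MAXNS + 1] = {0.0};
    for (size_t k = 0; k <= ns; ++k) { bb[k] = b[k]; aa[k] = a[k]; }
    for (size_t i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = bb[0] * xi + z[0];
      for (size_t k = 1; k <= MAXNS; ++k) {
        z[k - 1] = bb[k] * xi - aa[k] * yi + z[k];
      }
      z[MAXNS] = 0.0;
      x[i] = yi;
    }
    return;
  }
  std::vector<double> z(ns + 1, 0.0); // z[ns] stays 0 (sentinel)
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (size_t k = 1; k <= ns; ++k) {
      z[k - 1] = b[k] * xi - a[k] * yi + z[k];
    }
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering with reflected-edge padding,
// for normalised coefficients (a[0] == 1).
// [[Rcpp::export(name = ".iir_filtfilt")]]
NumericVector iir_filtfilt(NumericVector b, NumericVector a, NumericVector x,
                           int pad = 1000) {
  const int n = x.size();
  if (n == 0) return x;
  const int p = std::min(pad, n - 1);
  const size_t ns = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int k = 0; k < b.size(); ++k) bb[k] = b[k];
  for (int k = 0; k < a.size(); ++k) aa[k] = a[k];
  std::vector<double> xp(n + 2 * p);
  for (int i = 0; i < p; ++i) xp[i] = 2.0 * x[0] - x[p - i];
  for (int i = 0; i < n; ++i) xp[p + i] = x[i];
  for (int i = 0; i < p; ++i) xp[p + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  iir_pass(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());
  iir_pass(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xp[p + i];
  return out;
}

// Sum of consecutive groups of `every` elements (last group may be partial).
// [[Rcpp::export(name = ".group_sum")]]
NumericVector group_sum(NumericVector x, int every) {
  const int n = x.size();
  const int g = (n + every - 1) / every;
  NumericVector out(g);
  for (int i = 0; i < n; ++i) out[i / every] += x[i];
  return out;
}
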
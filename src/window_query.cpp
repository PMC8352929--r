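// Window queries over m/z-sorted ion arrays. R's findInterval re-checks
// sortedness (O(n)) on every call, which dominates at ~1e6 ions; these
// helpers assume the m/z vector is sorted (guaranteed by sample_ion_map).

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// first/last index (1-based) with lo <= mz_s[i] <= hi; c(0, -1) when empty
// [[Rcpp::export(name = ".mz_bounds")]]
IntegerVector mz_bounds(NumericVector mz_s, double lo, double hi) {
  const double *b = mz_s.begin(), *e = mz_s.end();
  const double *p1 = std::lower_bound(b, e, lo);
  const double *p2 = std::upper_bound(b, e, hi);
  return IntegerVector::create((int)(p1 - b) + 1, (int)(p2 - b));
}

// count / total intensity / signal intensity (> thr) inside the closed
// RT x m/z window
// [[Rcpp::export(name = ".extract_window")]]
NumericVector extract_window(NumericVector mz_s, NumericVector rt_s,
                             NumericVector int_s, double rt_lo,
                             double rt_hi, double mz_lo, double mz_hi,
                             double thr) {
  const double *b = mz_s.begin(), *e = mz_s.end();
  const int i1 = (int)(std::lower_bound(b, e, mz_lo) - b);
  const int i2 = (int)(std::upper_bound(b, e, mz_hi) - b);
  int n = 0;
  double total = 0.0, signal = 0.0;
  for (int i = i1; i < i2; ++i) {
    const double rt = rt_s[i];
    if (rt < rt_lo || rt > rt_hi) continue;
    ++n;
    total += int_s[i];
    if (int_s[i] > thr) signal += int_s[i];
  }
  return NumericVector::create((double)n, total, signal);
}
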
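#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Rolling percentile with edge-clipped centred windows, matching
// stats::quantile(type = 7) on each window exactly.
// [[Rcpp::export]]
NumericVector rolling_percentile_cpp(NumericVector x, int window,
                                     double prob) {
  const int n = x.size();
  const int half = window / 2;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(window + 1);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const int m = static_cast<int>(buf.size());
    // type-7: h = (m - 1) * p, linear interpolation between order stats
    double h = (m - 1) * prob;
    int lo_idx = static_cast<int>(std::floor(h));
    if (lo_idx > m - 1) lo_idx = m - 1;
    double g = h - lo_idx;
    std::nth_element(buf.begin(), buf.begin() + lo_idx, buf.end());
    double v_lo = buf[lo_idx];
    double v = v_lo;
    if (g > 0 && lo_idx + 1 <= m - 1) {
      double v_hi = *std::min_element(buf.begin() + lo_idx + 1, buf.end());
      v = v_lo + g * (v_hi - v_lo);
    }
    out[i] = v;
  }
  return out;
}
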
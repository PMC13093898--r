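#include <Rcpp.h>
using namespace Rcpp;

// Below-threshold local extrema: 1-based indices i with x[i] < thr[i] that
// are the minimum of x over the window [i - w, i + w], strictly smaller
// than every earlier sample in the window (so exact ties resolve to the
// earliest index).
// [[Rcpp::export]]
IntegerVector below_threshold_minima(NumericVector x, NumericVector thr,
                                     int w) {
  const int n = x.size();
  std::vector<int> out;
  for (int i = 0; i < n; ++i) {
    if (!(x[i] < thr[i])) continue;
    const int lo = std::max(0, i - w), hi = std::min(n - 1, i + w);
    bool is_min = true;
    for (int j = lo; j < i && is_min; ++j) is_min = x[i] < x[j];
    for (int j = i + 1; j <= hi && is_min; ++j) is_min = x[i] <= x[j];
    if (is_min) out.push_back(i + 1);
  }
  return wrap(out);
}
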
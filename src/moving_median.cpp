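#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of buf[0..m): for even m the mean of the two central order
// statistics, matching the documented even-window convention.
static double buffer_median(std::vector<double>& buf, int m) {
  int mid = m / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + m);
  double hi = buf[mid];
  if (m % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + mid);
  return (lo + hi) / 2.0;
}

// Running median over a window of `window` samples.
//
// centered = true: window covers [i - back, i + fwd] with back = window/2,
// fwd = window - back - 1 (for even windows one more sample behind than
// ahead). Near a segment edge the window is truncated symmetrically: with
// only b samples available behind and f ahead, h = min(b, f, back, fwd) and
// the window becomes [i - h, i + h].
//
// centered = false: trailing window [i - window + 1, i], truncated at the
// segment start.
//
// [[Rcpp::export]]
NumericVector moving_median_cpp(NumericVector x, int window, bool centered) {
  int n = x.size();
  NumericVector out(n);
  if (window < 1) stop("window must be >= 1");
  std::vector<double> buf(window);

  int back = window / 2;
  int fwd = window - back - 1;

  for (int i = 0; i < n; ++i) {
    int lo, hi; // inclusive
    if (centered) {
      int b = std::min(back, i);
      int f = std::min(fwd, n - 1 - i);
      if (b < back || f < fwd) {
        int h = std::min(b, f);
        lo = i - h;
        hi = i + h;
      } else {
        lo = i - back;
        hi = i + fwd;
      }
    } else {
      lo = std::max(0, i - window + 1);
      hi = i;
    }
    int m = hi - lo + 1;
    for (int j = 0; j < m; ++j) buf[j] = x[lo + j];
    out[i] = buffer_median(buf, m);
  }
  return out;
}
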
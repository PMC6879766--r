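#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding median over an epoch-indexed series.
// align: 0 = backward (window ends at i), 1 = forward (starts at i),
// 2 = centred. Windows are clipped at the series ends; NA values inside
// a window are ignored; positions where the input is NA stay NA
// (missing values propagate). Even-sized windows average the two
// central order statistics, matching stats::median.
// [[Rcpp::export]]
NumericVector roll_median_c(NumericVector x, int w, int align) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  std::vector<double> buf;
  buf.reserve(w);
  int h = w / 2;
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i])) continue;
    int lo, hi;
    if (align == 0) {
      lo = i - w + 1;
      hi = i;
    } else if (align == 1) {
      lo = i;
      hi = i + w - 1;
    } else {
      lo = i - h;
      hi = i + h;
    }
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    buf.clear();
    for (int j = lo; j <= hi; ++j) {
      if (!NumericVector::is_na(x[j])) buf.push_back(x[j]);
    }
    int m = buf.size();
    if (m == 0) continue;
    int mid = m / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (m % 2 == 0) {
      double lower = *std::max_element(buf.begin(), buf.begin() + mid);
      med = (med + lower) / 2.0;
    }
    out[i] = med;
  }
  return out;
}
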
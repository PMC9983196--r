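#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// k x k median filter with NA-aware neighborhoods: NA cells stay NA and are
// skipped when collecting neighbors. The window is clipped at matrix edges.
// [[Rcpp::export]]
NumericMatrix median_filter_mat(const NumericMatrix& x, int half) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  std::vector<double> buf;
  buf.reserve((2 * half + 1) * (2 * half + 1));
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      const double c = x(i, j);
      if (ISNAN(c)) { out(i, j) = NA_REAL; continue; }
      buf.clear();
      const int j0 = std::max(0, j - half), j1 = std::min(m - 1, j + half);
      const int i0 = std::max(0, i - half), i1 = std::min(n - 1, i + half);
      for (int jj = j0; jj <= j1; ++jj) {
        for (int ii = i0; ii <= i1; ++ii) {
          const double v = x(ii, jj);
          if (!ISNAN(v)) buf.push_back(v);
        }
      }
      const size_t k = buf.size();
      std::sort(buf.begin(), buf.end());
      out(i, j) = (k % 2) ? buf[k / 2] : 0.5 * (buf[k / 2 - 1] + buf[k / 2]);
    }
  }
  return out;
}
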
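#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All-against-all Jensen-Shannon divergence between the rows of a
// relative-abundance matrix. Uses the entropy identity
//   JSD(p, q) = H((p+q)/2) - (H(p) + H(q)) / 2
// with H in the requested log base; 0 * log 0 is taken as 0, so zeros need
// no pseudocounts. Returns the symmetric n x n divergence matrix.
// [[Rcpp::export(name = ".jsd_matrix_cpp")]]
NumericMatrix jsd_matrix_cpp(NumericMatrix x, double logbase) {
  const int n = x.nrow(), p = x.ncol();
  const double lb = std::log(logbase);
  NumericMatrix out(n, n);
  std::vector<double> h(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double hi = 0.0;
    for (int j = 0; j < p; ++j) {
      const double v = x(i, j);
      if (v > 0.0) hi -= v * std::log(v);
    }
    h[i] = hi / lb;
  }
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      double hm = 0.0;
      for (int j = 0; j < p; ++j) {
        const double m = 0.5 * (x(i, j) + x(k, j));
        if (m > 0.0) hm -= m * std::log(m);
      }
      hm /= lb;
      double d = hm - 0.5 * (h[i] + h[k]);
      if (d < 0.0) d = 0.0;  // guard tiny negative rounding
      out(i, k) = d;
      out(k, i) = d;
    }
  }
  return out;
}
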
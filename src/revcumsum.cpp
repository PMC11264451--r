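#include <Rcpp.h>
using namespace Rcpp;

// Columnwise reverse cumulative sums, accumulated from the largest row
// index upward so that small tail sums keep full precision (they feed the
// late Breslow risk sets, where a total-minus-prefix shortcut cancels
// catastrophically under extreme linear predictors).

// [[Rcpp::export]]
NumericMatrix rev_cumsum_cols_cpp(NumericMatrix m) {
  const int n = m.nrow(), p = m.ncol();
  NumericMatrix out(n, p);
  const double* src = m.begin();
  double* dst = out.begin();
  for (int j = 0; j < p; ++j) {
    const double* c = src + (std::size_t)j * n;
    double* o = dst + (std::size_t)j * n;
    double acc = 0.0;
    for (int i = n - 1; i >= 0; --i) {
      acc += c[i];
      o[i] = acc;
    }
  }
  return out;
}
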
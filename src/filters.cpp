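#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length nb-1).
// Coefficients must be normalized so a[0] == 1 and padded to equal length
// by the R caller.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                             NumericVector zi) {
  int nb = b.size(), n = x.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < nb - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[nb - 2] = b[nb - 1] * xi - a[nb - 1] * yi;
    y[i] = yi;
  }
  return y;
}
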
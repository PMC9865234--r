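// Direct-form II transposed IIR filter with explicit initial state,
// the building block of the zero-phase forward-backward filter.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  if (zi.size() != nz) stop("initial state has wrong length");
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(zi.begin(), zi.end());
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    y[i] = yi;
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
  }
  return y;
}
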
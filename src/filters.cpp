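#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length
// max(na, nb) - 1). a[0] must be 1. Returns the filtered signal; the
// state is not returned because zero-phase filtering recomputes it from
// the reversed pass anyway.
// [[Rcpp::export(name = ".lfilter_cpp")]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nz = std::max(na, nb) - 1;
  if ((int)zi.size() != nz) stop("zi must have length max(na, nb) - 1");
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < nz; ++i) z[i] = zi[i];
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi - aa[j + 1] * yi + z[j + 1];
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
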
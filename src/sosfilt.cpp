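#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi: n_sections x 2 initial state (may be empty for zero state).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x,
                          NumericMatrix zi) {
  int ns = sos.nrow();
  int n = x.size();
  NumericVector y = clone(x);
  std::vector<double> z1(ns, 0.0), z2(ns, 0.0);
  if (zi.nrow() == ns && zi.ncol() == 2) {
    for (int s = 0; s < ns; ++s) { z1[s] = zi(s, 0); z2[s] = zi(s, 1); }
  }
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = z1[s], w2 = z2[s];
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
    z1[s] = w1; z2[s] = w2;
  }
  return y;
}
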
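#include <Rcpp.h>
using namespace Rcpp;

// One biquad pass (direct form II transposed) with initial state z scaled to
// the signal's first sample, suppressing the start-up transient.
static void biquad_inplace(std::vector<double>& x, double b0, double b1,
                           double b2, double a1, double a2, double zi1,
                           double zi2) {
  double z1 = zi1 * x[0], z2 = zi2 * x[0];
  for (size_t i = 0; i < x.size(); ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    x[i] = yi;
  }
}

// Zero-phase cascade of biquad sections: forward and reverse pass per
// section, each started from its steady-state response to a constant input
// (the lfilter_zi construction).
// sos: L x 5 matrix, rows (b0, b1, b2, a1, a2) with a0 = 1.
// [[Rcpp::export]]
NumericVector sosfiltfilt_rcpp(NumericMatrix sos, NumericVector x) {
  const int n = x.size(), L = sos.nrow();
  std::vector<double> y(x.begin(), x.end());
  for (int s = 0; s < L; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 3), a2 = sos(s, 4);
    // steady state: solve (I - A^T) z = B with
    // A^T = [[-a1, 1], [-a2, 0]], B = [b1 - b0*a1, b2 - b0*a2]
    const double B1 = b1 - b0 * a1, B2 = b2 - b0 * a2;
    // (1 + a1) z1 - z2 = B1 ; a2 z1 + z2 = B2  =>
    const double z1 = (B1 + B2) / (1.0 + a1 + a2);
    const double z2 = B2 - a2 * z1;
    biquad_inplace(y, b0, b1, b2, a1, a2, z1, z2);
    std::reverse(y.begin(), y.end());
    biquad_inplace(y, b0, b1, b2, a1, a2, z1, z2);
    std::reverse(y.begin(), y.end());
  }
  return NumericVector(y.begin(), y.end());
}
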
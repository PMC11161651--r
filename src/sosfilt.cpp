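// Second-order-section IIR filtering with steady-state initial conditions.
//
// Each biquad runs in direct-form II transposed. The filter state is
// initialized to its steady-state response for a step of the first sample
// value (the lfilter_zi construction), which removes the start-up
// transient that a zero-state filter exhibits at cut-off frequencies far
// below the sampling rate. In zero-phase mode each section is applied
// forward and then backward with the same initialization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void biquad(vec& x, double b0, double b1, double b2,
                   double a1, double a2, bool reverse) {
  const int n = x.n_elem;
  // steady-state (unit-step) state for direct-form II transposed
  const double denom = 1.0 + a1 + a2;
  const double yss = (std::abs(denom) > 1e-300)
    ? (b0 + b1 + b2) / denom : 0.0;
  const double zi1 = yss - b0;
  const double zi2 = b2 - a2 * yss;
  const int first = reverse ? n - 1 : 0;
  const int step = reverse ? -1 : 1;
  double z1 = zi1 * x[first], z2 = zi2 * x[first];
  for (int i = first, c = 0; c < n; i += step, ++c) {
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    x[i] = yi;
  }
}

// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// [[Rcpp::export]]
arma::vec sosfilt(const arma::vec& x, const arma::mat& sos, bool zero_phase) {
  vec y = x;
  for (uword s = 0; s < sos.n_rows; ++s) {
    biquad(y, sos(s, 0), sos(s, 1), sos(s, 2), sos(s, 4), sos(s, 5), false);
    if (zero_phase)
      biquad(y, sos(s, 0), sos(s, 1), sos(s, 2), sos(s, 4), sos(s, 5), true);
  }
  return y;
}
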
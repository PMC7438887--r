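#include <Rcpp.h>
using namespace Rcpp;

// Delta-modulator tracking loop over the linearly interpolated signal.
// Interpolated points are never materialized: with interpolation factor m,
// point k (0-based, k = 0 .. (n-1)*m) lies between samples floor(k/m) and
// floor(k/m)+1 and carries time k * 1e6 / (rate * m) microseconds.
// The tracking reference r starts at the first sample and moves by +/- delta
// when the signal departs from it by more than delta; at most one spike is
// emitted per interpolated point.
// [[Rcpp::export]]
List delta_mod_encode_cpp(NumericVector x, double rate_hz, int interp,
                          double delta) {
  const R_xlen_t n = x.size();
  std::vector<double> up, down;
  if (n >= 2) {
    const double dt_us = 1e6 / (rate_hz * interp);
    double r = x[0];
    for (R_xlen_t i = 0; i < n - 1; ++i) {
      const double x0 = x[i], slope = (x[i + 1] - x[i]) / interp;
      // k = 0 of segment i coincides with sample i (already visited); the
      // very first point of the signal only initializes r and never spikes.
      for (int k = 1; k <= interp; ++k) {
        const double s = x0 + slope * k;
        const double t = (static_cast<double>(i) * interp + k) * dt_us;
        // trigger at >= delta (tiny tolerance so that exact multiples of
        // delta, e.g. a full-range ramp, emit floor(range/delta) spikes)
        if (s - r >= delta - 1e-12) {
          up.push_back(t);
          r += delta;
        } else if (r - s >= delta - 1e-12) {
          down.push_back(t);
          r -= delta;
        }
      }
    }
  }
  return List::create(_["up"] = wrap(up), _["down"] = wrap(down));
}
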
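#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear-chirp sweep law shared with the R side (sweep_frequency/sweep_phase in
// R/kelvin_voigt.R must stay in exact agreement): the drive holds f_from for
// `settle` seconds, then the instantaneous frequency ramps linearly at `rate`
// Hz/s (signed; negative for a down sweep).
static inline double chirp_freq(double t, double f_from, double rate,
                                double settle) {
  if (t <= settle) return f_from;
  return f_from + rate * (t - settle);
}

static inline double chirp_phase(double t, double f_from, double rate,
                                 double settle) {
  if (t <= settle) return 2.0 * M_PI * f_from * t;
  double tau = t - settle;
  return 2.0 * M_PI * (f_from * settle + f_from * tau + 0.5 * rate * tau * tau);
}

struct DuffingSystem {
  double m, k, c, beta, A, f_from, rate, settle;
  // state derivative: base-excited element, spring and damper both acting on
  // the strip extension e = u - x; cubic stiffness correction beta * e^2.
  inline void deriv(double t, double x, double v, double &dx, double &dv) const {
    double ph = chirp_phase(t, f_from, rate, settle);
    double f = chirp_freq(t, f_from, rate, settle);
    double u = A * sin(ph);
    double du = A * 2.0 * M_PI * f * cos(ph);
    double e = u - x;
    dx = v;
    dv = (k * e * (1.0 + beta * e * e) + c * (du - v)) / m;
  }
};

// [[Rcpp::export(name = ".duffing_response")]]
NumericVector duffing_response(int n, double fs, double m, double k, double c,
                               double beta, double A, double f_from,
                               double rate, double settle, int n_sub) {
  if (n < 2) stop("need at least 2 samples");
  if (n_sub < 1) stop("n_sub must be >= 1");
  DuffingSystem sys{m, k, c, beta, A, f_from, rate, settle};

  NumericVector out(n);
  double h = 1.0 / (fs * (double)n_sub);
  // start riding with the base so the settle segment only has to absorb the
  // residual transient, not a cold start
  double x = 0.0;
  double v = A * 2.0 * M_PI * f_from;
  out[0] = x;

  double k1x, k1v, k2x, k2v, k3x, k3v, k4x, k4v;
  for (int i = 1; i < n; ++i) {
    double t0 = (double)(i - 1) / fs;  // re-anchor to avoid drift of t
    for (int s = 0; s < n_sub; ++s) {
      double t = t0 + h * (double)s;
      sys.deriv(t, x, v, k1x, k1v);
      sys.deriv(t + 0.5 * h, x + 0.5 * h * k1x, v + 0.5 * h * k1v, k2x, k2v);
      sys.deriv(t + 0.5 * h, x + 0.5 * h * k2x, v + 0.5 * h * k2v, k3x, k3v);
      sys.deriv(t + h, x + h * k3x, v + h * k3v, k4x, k4v);
      x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
      v += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    }
    if (!std::isfinite(x) || !std::isfinite(v))
      stop("integrator diverged at t = %g s: step too large or non-physical "
           "parameters", (double)i / fs);
    out[i] = x;
  }
  return out;
}
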
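#include <Rcpp.h>
using namespace Rcpp;

// Brute-force fixed-step integrators (forward Euler and classical RK4) used
// as an independent cross-check of the adaptive solver. Deliberately simple:
// no error control, no step adaptation.

static inline void rhs(const double y[3], double mu, double m, double c,
                       double se, double si, double dy[3]) {
  const double n = y[0], i = y[1], e = y[2];
  dy[0] = m * i + m * e - n * e * se - n * i * si;
  dy[1] = -mu * i - m * i + n * i * si + (1.0 - c) * e * i * si -
          (1.0 - c) * i * e * se;
  dy[2] = mu * i - m * e + n * e * se - (1.0 - c) * e * i * si +
          (1.0 - c) * i * e * se;
}

// [[Rcpp::export(name = ".fixed_step_cpp")]]
NumericMatrix fixed_step_cpp(NumericVector y0, double mu, double m, double c,
                             double se, double si, NumericVector out_times,
                             double h, int method) {
  // method: 1 = Euler, 4 = RK4; out_times[0] must be 0
  const int n_out = out_times.size();
  NumericMatrix out(n_out, 3);
  double y[3] = {y0[0], y0[1], y0[2]};
  for (int k = 0; k < 3; ++k) out(0, k) = y[k];
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  for (int j = 1; j < n_out; ++j) {
    const double span = out_times[j] - out_times[j - 1];
    // step count chosen so the nominal step h divides the interval; when the
    // output grid is commensurate with h this is exactly fixed-step
    long nsteps = (long)std::llround(span / h);
    if (nsteps < 1) nsteps = 1;
    const double hh = span / (double)nsteps;
    for (long s = 0; s < nsteps; ++s) {
      if (method == 1) {
        rhs(y, mu, m, c, se, si, k1);
        for (int k = 0; k < 3; ++k) y[k] += hh * k1[k];
      } else {
        rhs(y, mu, m, c, se, si, k1);
        for (int k = 0; k < 3; ++k) tmp[k] = y[k] + 0.5 * hh * k1[k];
        rhs(tmp, mu, m, c, se, si, k2);
        for (int k = 0; k < 3; ++k) tmp[k] = y[k] + 0.5 * hh * k2[k];
        rhs(tmp, mu, m, c, se, si, k3);
        for (int k = 0; k < 3; ++k) tmp[k] = y[k] + hh * k3[k];
        rhs(tmp, mu, m, c, se, si, k4);
        for (int k = 0; k < 3; ++k)
          y[k] += hh * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]) / 6.0;
      }
    }
    for (int k = 0; k < 3; ++k) out(j, k) = y[k];
  }
  return out;
}
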
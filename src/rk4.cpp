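#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 for the two coupled flows. Both systems are non-stiff on
// their attractors, so a fixed step keeps runs bit-reproducible across
// platforms with identical inputs.

static inline void rl_field(const double* s, double* ds, double a, double C) {
  // Roessler subsystem with time-scale factor a, driving a Lorenz subsystem
  // through C * x2^2 in the second Lorenz equation.
  ds[0] = -a * (s[1] + s[2]);
  ds[1] =  a * (s[0] + 0.2 * s[1]);
  ds[2] =  a * (0.2 + s[2] * (s[0] - 5.7));
  ds[3] = 10.0 * (-s[3] + s[4]);
  ds[4] = 28.0 * s[3] - s[4] - s[3] * s[5] + C * s[1] * s[1];
  ds[5] = s[3] * s[4] - (8.0 / 3.0) * s[5];
}

static inline void rr_field(const double* s, double* ds,
                            double om1, double om2,
                            double a1, double a2, double b1, double b2,
                            double c, double C, int y3_standard) {
  ds[0] = -om1 * s[1] - s[2];
  ds[1] =  om1 * s[0] + a1 * s[1];
  ds[2] =  s[2] * (s[0] - c) + b1;
  ds[3] = -om2 * s[4] - s[5] + C * (s[0] - s[3]);
  ds[4] =  om2 * s[3] + a2 * s[4];
  ds[5] =  y3_standard ? (s[5] * (s[3] - c) + b2) : (s[5] * (s[3] + c) + b2);
}

template <typename Field>
static NumericMatrix rk4_run(NumericVector state0, double dt,
                             int n_burn, int n_keep, int keep_every,
                             Field field) {
  const int d = 6;
  double s[6], k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int i = 0; i < d; ++i) s[i] = state0[i];
  NumericMatrix out(n_keep, d);

  long total = (long)n_burn + (long)(n_keep - 1) * keep_every;
  int kept = 0;
  for (long step = 0; step <= total; ++step) {
    if (step >= n_burn && (step - n_burn) % keep_every == 0) {
      for (int i = 0; i < d; ++i) out(kept, i) = s[i];
      ++kept;
      if (kept == n_keep) break;
    }
    field(s, k1);
    for (int i = 0; i < d; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    field(tmp, k2);
    for (int i = 0; i < d; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    field(tmp, k3);
    for (int i = 0; i < d; ++i) tmp[i] = s[i] + dt * k3[i];
    field(tmp, k4);
    for (int i = 0; i < d; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < d; ++i)
      if (!R_finite(s[i])) stop("non-finite state during integration at step %ld", step);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix rk4_rossler_lorenz_cpp(NumericVector state0, double a, double C,
                                     double dt, int n_burn, int n_keep,
                                     int keep_every) {
  return rk4_run(state0, dt, n_burn, n_keep, keep_every,
                 [a, C](const double* s, double* ds) { rl_field(s, ds, a, C); });
}

// [[Rcpp::export]]
NumericMatrix rk4_rossler_rossler_cpp(NumericVector state0,
                                      double om1, double om2,
                                      double a1, double a2,
                                      double b1, double b2,
                                      double c, double C,
                                      double dt, int n_burn, int n_keep,
                                      int keep_every, int y3_standard) {
  return rk4_run(state0, dt, n_burn, n_keep, keep_every,
                 [=](const double* s, double* ds) {
                   rr_field(s, ds, om1, om2, a1, a2, b1, b2, c, C, y3_standard);
                 });
}

// Single vector-field evaluations, used by unit tests that substitute states
// directly into the governing equations.

// [[Rcpp::export]]
NumericVector rl_field_cpp(NumericVector state, double a, double C) {
  NumericVector ds(6);
  rl_field(REAL(state), REAL(ds), a, C);
  return ds;
}

// [[Rcpp::export]]
NumericVector rr_field_cpp(NumericVector state, double om1, double om2,
                           double a1, double a2, double b1, double b2,
                           double c, double C, int y3_standard) {
  NumericVector ds(6);
  rr_field(REAL(state), REAL(ds), om1, om2, a1, a2, b1, b2, c, C, y3_standard);
  return ds;
}
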
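#include <Rcpp.h>
#include "tp06.h"
using namespace Rcpp;

// Published initial values (epicardial cell, as distributed with the model).
// [[Rcpp::export]]
NumericVector cpp_tp06_default_state() {
  NumericVector y(TP06_NSTATE);
  y[0] = -86.2;   // V
  y[1] = 0.0;     // m
  y[2] = 0.75;    // h
  y[3] = 0.75;    // j
  y[4] = 0.0;     // xr1
  y[5] = 1.0;     // xr2
  y[6] = 0.0;     // xs
  y[7] = 0.0;     // r
  y[8] = 1.0;     // s
  y[9] = 0.0;     // d
  y[10] = 1.0;    // f
  y[11] = 1.0;    // f2
  y[12] = 1.0;    // fcass
  y[13] = 1.0;    // rbar
  y[14] = 7.67;   // nai
  y[15] = 138.3;  // ki
  y[16] = 0.00007; // cai
  y[17] = 0.00007; // cass
  y[18] = 1.3;    // casr
  y.attr("names") = CharacterVector::create(
      "V", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
      "fcass", "rbar", "nai", "ki", "cai", "cass", "casr");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_tp06_rhs(NumericVector y, double stim) {
  if (y.size() != TP06_NSTATE) stop("state must have %d components", TP06_NSTATE);
  NumericVector dy(TP06_NSTATE);
  tp06::rhs(REAL(y), stim, REAL(dy));
  dy.attr("names") = cpp_tp06_default_state().attr("names");
  return dy;
}

static void check_finite(const double *y, double t) {
  static const char *nm[TP06_NSTATE] = {"V", "m", "h", "j", "xr1", "xr2",
      "xs", "r", "s", "d", "f", "f2", "fcass", "rbar", "nai", "ki", "cai",
      "cass", "casr"};
  for (int i = 0; i < TP06_NSTATE; i++)
    if (!std::isfinite(y[i]))
      stop("numerical blow-up: state component '%s' became non-finite at t = %.3f ms (reduce dt)",
           nm[i], t);
}

// Single-cell integration with Rush-Larsen (or forward-Euler) gate updates.
// Records the full state every `record_every` steps (0 = only final state).
// [[Rcpp::export]]
List cpp_tp06_integrate(NumericVector y0, double dt, int n_steps,
                        double stim_amp, double stim_start, double stim_dur,
                        int record_every, bool gates_fe) {
  if (y0.size() != TP06_NSTATE) stop("bad state length");
  double y[TP06_NSTATE];
  std::copy(y0.begin(), y0.end(), y);
  int n_rec = record_every > 0 ? n_steps / record_every + 1 : 0;
  NumericMatrix rec(n_rec > 0 ? n_rec : 0, TP06_NSTATE + 1);
  int ir = 0;
  if (record_every > 0) {
    rec(0, 0) = 0.0;
    for (int c = 0; c < TP06_NSTATE; c++) rec(0, c + 1) = y[c];
    ir = 1;
  }
  double dy[TP06_NSTATE];
  for (int n = 0; n < n_steps; n++) {
    double t = n * dt;
    double stim = (t >= stim_start && t < stim_start + stim_dur) ? stim_amp : 0.0;
    if (!gates_fe) {
      tp06::step_rl(y, dt, stim);
    } else {
      tp06::rhs(y, stim, dy);
      for (int c = 0; c < TP06_NSTATE; c++) y[c] += dt * dy[c];
      // forward-Euler gate updates overshoot for the fastest gates
      // (tau_m < dt near rest); gating fractions are clamped to [0, 1]
      for (int c = 1; c <= 13; c++) {
        if (y[c] < 0.0) y[c] = 0.0;
        if (y[c] > 1.0) y[c] = 1.0;
      }
    }
    if ((n & 255) == 0) check_finite(y, t);
    if (record_every > 0 && ((n + 1) % record_every == 0) && ir < n_rec) {
      rec(ir, 0) = (n + 1) * dt;
      for (int c = 0; c < TP06_NSTATE; c++) rec(ir, c + 1) = y[c];
      ir++;
    }
  }
  check_finite(y, n_steps * dt);
  NumericVector yf(y, y + TP06_NSTATE);
  yf.attr("names") = cpp_tp06_default_state().attr("names");
  return List::create(_["state"] = yf, _["trace"] = rec);
}
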
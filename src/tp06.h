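#ifndef EGMSIM_TP06_H
#define EGMSIM_TP06_H

#include <cmath>

// ten Tusscher & Panfilov (2006) human ventricular membrane model,
// epicardial parameter set.  State layout (19 doubles per cell):
//   0 V      transmembrane voltage            mV
//   1 m      INa activation
//   2 h      INa fast inactivation
//   3 j      INa slow inactivation
//   4 xr1    IKr activation
//   5 xr2    IKr inactivation
//   6 xs     IKs activation
//   7 r      Ito activation
//   8 s      Ito inactivation
//   9 d      ICaL activation
//  10 f      ICaL voltage inactivation
//  11 f2     ICaL slow voltage inactivation
//  12 fcass  ICaL subspace-Ca inactivation
//  13 rbar   fraction of closed-and-ready RyR (CICR)
//  14 nai    intracellular Na+                mM
//  15 ki     intracellular K+                 mM
//  16 cai    cytosolic free Ca2+              mM
//  17 cass   subspace free Ca2+               mM
//  18 casr   SR free Ca2+                     mM
// Time in ms, currents in pA/pF.  Stimulus convention: a positive
// stim argument depolarizes.

#define TP06_NSTATE 19

namespace tp06 {

// physical constants
const double Rgas = 8314.472;     // mJ/(mol K)
const double Frdy = 96485.3415;   // C/mol
const double Temp = 310.0;        // K
const double RTF  = Rgas * Temp / Frdy;
const double invRTF = 1.0 / RTF;

// external concentrations (mM)
const double Ko  = 5.4;
const double Nao = 140.0;
const double Cao = 2.0;

// cell geometry / capacitance (as in the published source)
const double Vc   = 0.016404;
const double Vsr  = 0.001094;
const double Vss  = 0.00005468;
const double Cap  = 0.185;        // "CAPACITANCE" scaling of flux terms

// buffering
const double Bufc   = 0.2,  Kbufc  = 0.001;
const double Bufsr  = 10.0, Kbufsr = 0.3;
const double Bufss  = 0.4,  Kbufss = 0.00025;

// SR fluxes / CICR
const double Vmaxup = 0.006375, Kup = 0.00025;
const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
const double EC = 1.5, maxsr = 2.5, minsr = 1.0;

// maximal conductances (epicardial)
const double GNa  = 14.838;
const double GK1  = 5.405;
const double Gto  = 0.294;
const double GKr  = 0.153;
const double GKs  = 0.392;
const double GCaL = 0.0000398;
const double GbNa = 0.00029;
const double GbCa = 0.000592;
const double GpCa = 0.1238, KpCa = 0.0005;
const double GpK  = 0.0146;
const double PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
const double kNaCa = 1000.0, ksat = 0.1, alpha_naca = 2.5;
const double gamma_naca = 0.35, KmCa = 1.38, KmNai = 87.5;
const double PKNa = 0.03;

// Voltage-dependent gate kinetics: steady state and time constant.
struct GateVals { double inf, tau; };

inline GateVals gate_m(double V) {
  GateVals g;
  double a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
             0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  g.inf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
  g.tau = a * b;
  return g;
}

inline GateVals gate_h(double V) {
  GateVals g;
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.057 * std::exp(-(V + 80.0) / 6.8);
    b = 2.7 * std::exp(0.079 * V) + 310000.0 * std::exp(0.3485 * V);
  }
  g.inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
  g.tau = 1.0 / (a + b);
  return g;
}

inline GateVals gate_j(double V) {
  GateVals g;
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-25428.0 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.02424 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  g.inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
  g.tau = 1.0 / (a + b);
  return g;
}

inline GateVals gate_xr1(double V) {
  GateVals g;
  double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  g.inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  g.tau = a * b;
  return g;
}

inline GateVals gate_xr2(double V) {
  GateVals g;
  double a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  g.inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  g.tau = a * b;
  return g;
}

inline GateVals gate_xs(double V) {
  GateVals g;
  double a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  double b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  g.inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  g.tau = a * b + 80.0;
  return g;
}

inline GateVals gate_r(double V) {
  GateVals g;
  g.inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  g.tau = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  return g;
}

// epicardial variant
inline GateVals gate_s(double V) {
  GateVals g;
  g.inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  g.tau = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
          5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  return g;
}

inline GateVals gate_d(double V) {
  GateVals g;
  double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  g.inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  g.tau = a * b + c;
  return g;
}

inline GateVals gate_f(double V) {
  GateVals g;
  g.inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  g.tau = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
          200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
          180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  return g;
}

inline GateVals gate_f2(double V) {
  GateVals g;
  g.inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  g.tau = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
          31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
          80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  return g;
}

// subspace-calcium gate (not voltage dependent)
inline GateVals gate_fcass(double cass) {
  GateVals g;
  double q = (cass / 0.05) * (cass / 0.05);
  g.inf = 0.6 / (1.0 + q) + 0.4;
  g.tau = 80.0 / (1.0 + q) + 2.0;
  return g;
}

// ICaL driving-force split: ICaL = GCaL*d*f*f2*fcass*(c1(V)*cass - c2(V))
inline void ical_coefs(double V, double &c1, double &c2) {
  double vf = (V - 15.0) * invRTF;
  double pre = 4.0 * (V - 15.0) * Frdy * invRTF;   // 4 (V-15) F^2/(RT)
  if (std::fabs(vf) < 1e-5) {
    // limit V -> 15 mV of  pre * e2v/(e2v-1)  and  pre/(e2v-1)
    c1 = 4.0 * Frdy / invRTF * invRTF * 0.25;      // = 4 F * RT^{-1}... see below
    // Careful limit: pre/(exp(2vf)-1) -> 4*F/ (2/RTF... ) use series:
    // pre = 4*(V-15)*F/RTF ; exp(2vf)-1 ~ 2vf = 2(V-15)/RTF
    // => pre/(exp(2vf)-1) -> 2*F
    c1 = 0.25 * 2.0 * Frdy;                        // 0.25*cass coefficient
    c2 = Cao * 2.0 * Frdy;
  } else {
    double e2 = std::exp(2.0 * vf);
    c1 = pre * 0.25 * e2 / (e2 - 1.0);
    c2 = pre * Cao / (e2 - 1.0);
  }
  // note: pre has units pA/pF per mM when multiplied by GCaL
}

// Full right-hand side evaluation (for a single cell).
// stim > 0 depolarizes. dy must hold TP06_NSTATE doubles.
inline void rhs(const double *y, double stim, double *dy) {
  const double V = y[0], m = y[1], h = y[2], j = y[3];
  const double xr1 = y[4], xr2 = y[5], xs = y[6], r = y[7], s = y[8];
  const double d = y[9], f = y[10], f2 = y[11], fcass = y[12];
  const double rbar = y[13];
  const double nai = y[14], ki = y[15];
  const double cai = y[16], cass = y[17], casr = y[18];

  const double EK  = RTF * std::log(Ko / ki);
  const double ENa = RTF * std::log(Nao / nai);
  const double EKs = RTF * std::log((Ko + PKNa * Nao) / (ki + PKNa * nai));
  const double ECa = 0.5 * RTF * std::log(Cao / cai);

  const double INa = GNa * m * m * m * h * j * (V - ENa);

  double c1, c2;
  ical_coefs(V, c1, c2);
  const double ICaL = GCaL * d * f * f2 * fcass * (c1 * cass - c2);

  const double Ito = Gto * r * s * (V - EK);
  const double IKr = GKr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
  const double IKs = GKs * xs * xs * (V - EKs);

  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                      std::exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = GK1 * std::sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  const double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * invRTF) +
                             0.0353 * std::exp(-V * invRTF));
  const double INaK = PNaK * Ko / (Ko + KmK) * nai / (nai + KmNa) * fnak;

  const double ea = std::exp(gamma_naca * V * invRTF);
  const double eb = std::exp((gamma_naca - 1.0) * V * invRTF);
  const double denom = (KmNai * KmNai * KmNai + Nao * Nao * Nao) *
                       (KmCa + Cao) * (1.0 + ksat * eb);
  const double INaCa = kNaCa *
      (ea * nai * nai * nai * Cao - eb * Nao * Nao * Nao * cai * alpha_naca) /
      denom;

  const double IpCa = GpCa * cai / (cai + KpCa);
  const double IpK  = GpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - ENa);
  const double IbCa = GbCa * (V - ECa);

  const double Istim = -stim;   // published sign convention (negative = depolarizing)
  const double Itot = INa + ICaL + Ito + IKr + IKs + IK1 + INaK + INaCa +
                      IpCa + IpK + IbNa + IbCa + Istim;
  dy[0] = -Itot;

  GateVals g;
  g = gate_m(V);   dy[1] = (g.inf - m)   / g.tau;
  g = gate_h(V);   dy[2] = (g.inf - h)   / g.tau;
  g = gate_j(V);   dy[3] = (g.inf - j)   / g.tau;
  g = gate_xr1(V); dy[4] = (g.inf - xr1) / g.tau;
  g = gate_xr2(V); dy[5] = (g.inf - xr2) / g.tau;
  g = gate_xs(V);  dy[6] = (g.inf - xs)  / g.tau;
  g = gate_r(V);   dy[7] = (g.inf - r)   / g.tau;
  g = gate_s(V);   dy[8] = (g.inf - s)   / g.tau;
  g = gate_d(V);   dy[9] = (g.inf - d)   / g.tau;
  g = gate_f(V);   dy[10] = (g.inf - f)  / g.tau;
  g = gate_f2(V);  dy[11] = (g.inf - f2) / g.tau;
  g = gate_fcass(cass); dy[12] = (g.inf - fcass) / g.tau;

  // CICR
  const double kcasr = maxsr - (maxsr - minsr) / (1.0 + (EC / casr) * (EC / casr));
  const double k1 = k1p / kcasr;
  const double k2 = k2p * kcasr;
  dy[13] = -k2 * cass * rbar + k4 * (1.0 - rbar);
  const double Orel = k1 * cass * cass * rbar / (k3 + k1 * cass * cass);
  const double Irel = Vrel * Orel * (casr - cass);
  const double Ileak = Vleak * (casr - cai);
  const double Iup = Vmaxup / (1.0 + (Kup / cai) * (Kup / cai));
  const double Ixfer = Vxfer * (cass - cai);

  const double bufc = 1.0 / (1.0 + Bufc * Kbufc / ((cai + Kbufc) * (cai + Kbufc)));
  const double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((casr + Kbufsr) * (casr + Kbufsr)));
  const double bufss = 1.0 / (1.0 + Bufss * Kbufss / ((cass + Kbufss) * (cass + Kbufss)));

  dy[16] = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                   (IbCa + IpCa - 2.0 * INaCa) * Cap / (2.0 * Vc * Frdy));
  dy[18] = bufsr * (Iup - Irel - Ileak);
  dy[17] = bufss * (-Ixfer * Vc / Vss + Irel * Vsr / Vss -
                    ICaL * Cap / (2.0 * Vss * Frdy));

  dy[14] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cap / (Vc * Frdy);
  dy[15] = -(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK + Istim) * Cap / (Vc * Frdy);
}

// One operator-split substep: Rush-Larsen for the 12 gates tabulated in V,
// exponential update for fcass, forward Euler for V and concentrations.
// Non-LUT version (used for single-cell work and as reference).
inline void step_rl(double *y, double dt, double stim) {
  double dy[TP06_NSTATE];
  rhs(y, stim, dy);           // dy used for V, concentrations, rbar
  const double V = y[0];
  GateVals g;
  g = gate_m(V);   y[1]  = g.inf + (y[1]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_h(V);   y[2]  = g.inf + (y[2]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_j(V);   y[3]  = g.inf + (y[3]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_xr1(V); y[4]  = g.inf + (y[4]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_xr2(V); y[5]  = g.inf + (y[5]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_xs(V);  y[6]  = g.inf + (y[6]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_r(V);   y[7]  = g.inf + (y[7]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_s(V);   y[8]  = g.inf + (y[8]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_d(V);   y[9]  = g.inf + (y[9]  - g.inf) * std::exp(-dt / g.tau);
  g = gate_f(V);   y[10] = g.inf + (y[10] - g.inf) * std::exp(-dt / g.tau);
  g = gate_f2(V);  y[11] = g.inf + (y[11] - g.inf) * std::exp(-dt / g.tau);
  g = gate_fcass(y[17]); y[12] = g.inf + (y[12] - g.inf) * std::exp(-dt / g.tau);
  y[0]  += dt * dy[0];
  y[13] += dt * dy[13];
  y[14] += dt * dy[14];
  y[15] += dt * dy[15];
  y[16] += dt * dy[16];
  y[17] += dt * dy[17];
  y[18] += dt * dy[18];
}

}  // namespace tp06

#endif
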
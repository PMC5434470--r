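# Independent oracles used across the test suite.

# --- ten Tusscher-Panfilov 2006 (epicardial) right-hand side, written
# directly from the published equations for use with deSolve's stiff
# integrators as an independent check on the compiled stepper. ---
tp06_rhs_oracle <- function(t, y, parms) {
  V <- y[1]; m <- y[2]; h <- y[3]; j <- y[4]; xr1 <- y[5]; xr2 <- y[6]
  xs <- y[7]; r <- y[8]; s <- y[9]; d <- y[10]; f <- y[11]; f2 <- y[12]
  fcass <- y[13]; rbar <- y[14]; nai <- y[15]; ki <- y[16]
  cai <- y[17]; cass <- y[18]; casr <- y[19]

  R <- 8314.472; Fd <- 96485.3415; Temp <- 310
  RTF <- R * Temp / Fd
  Ko <- 5.4; Nao <- 140; Cao <- 2
  Vc <- 0.016404; Vsr <- 0.001094; Vss <- 5.468e-5; Cap <- 0.185

  EK <- RTF * log(Ko / ki); ENa <- RTF * log(Nao / nai)
  EKs <- RTF * log((Ko + 0.03 * Nao) / (ki + 0.03 * nai))
  ECa <- 0.5 * RTF * log(Cao / cai)

  INa <- 14.838 * m^3 * h * j * (V - ENa)
  vf <- (V - 15) / RTF
  ICaL <- if (abs(vf) < 1e-7)
    3.98e-5 * d * f * f2 * fcass * 2 * Fd * (0.25 * cass - Cao)
  else
    3.98e-5 * d * f * f2 * fcass * 4 * (V - 15) * Fd / RTF *
      (0.25 * cass * exp(2 * vf) - Cao) / (exp(2 * vf) - 1)
  Ito <- 0.294 * r * s * (V - EK)
  IKr <- 0.153 * sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK)
  IKs <- 0.392 * xs^2 * (V - EKs)
  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(2e-4 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- 5.405 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK)
  INaK <- 2.724 * Ko / (Ko + 1) * nai / (nai + 40) /
    (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF))
  INaCa <- 1000 * (exp(0.35 * V / RTF) * nai^3 * Cao -
                   exp(-0.65 * V / RTF) * Nao^3 * cai * 2.5) /
    ((87.5^3 + Nao^3) * (1.38 + Cao) * (1 + 0.1 * exp(-0.65 * V / RTF)))
  IpCa <- 0.1238 * cai / (cai + 5e-4)
  IpK <- 0.0146 * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbNa <- 2.9e-4 * (V - ENa)
  IbCa <- 5.92e-4 * (V - ECa)

  Istim <- -parms$stim(t)
  Itot <- INa + ICaL + Ito + IKr + IKs + IK1 + INaK + INaCa + IpCa + IpK +
    IbNa + IbCa + Istim

  gate <- function(g, inf, tau) (inf - g) / tau
  minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  mtau <- 1 / (1 + exp((-60 - V) / 5)) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) {
    ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
  }
  jinf <- hinf
  if (V >= -40) {
    aj <- 0; bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    aj <- (-25428 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  xr1inf <- 1 / (1 + exp((-26 - V) / 7))
  xr1tau <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
  xr2inf <- 1 / (1 + exp((V + 88) / 24))
  xr2tau <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
  xsinf <- 1 / (1 + exp((-5 - V) / 14))
  xstau <- 1400 / sqrt(1 + exp((5 - V) / 6)) / (1 + exp((V - 35) / 15)) + 80
  rinf <- 1 / (1 + exp((20 - V) / 6))
  rtau <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  sinf <- 1 / (1 + exp((V + 20) / 5))
  stau <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  dinf <- 1 / (1 + exp((-8 - V) / 7.5))
  dtau <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    1.4 / (1 + exp((V + 5) / 5)) + 1 / (1 + exp((50 - V) / 20))
  finf <- 1 / (1 + exp((V + 20) / 7))
  ftau <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  f2tau <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  q <- (cass / 0.05)^2
  fcassinf <- 0.6 / (1 + q) + 0.4
  fcasstau <- 80 / (1 + q) + 2

  kcasr <- 2.5 - 1.5 / (1 + (1.5 / casr)^2)
  k1 <- 0.15 / kcasr; k2 <- 0.045 * kcasr
  drbar <- -k2 * cass * rbar + 0.005 * (1 - rbar)
  O <- k1 * cass^2 * rbar / (0.06 + k1 * cass^2)
  Irel <- 0.102 * O * (casr - cass)
  Ileak <- 3.6e-4 * (casr - cai)
  Iup <- 0.006375 / (1 + (2.5e-4 / cai)^2)
  Ixfer <- 0.0038 * (cass - cai)
  bufc <- 1 / (1 + 0.2 * 0.001 / (cai + 0.001)^2)
  bufsr <- 1 / (1 + 10 * 0.3 / (casr + 0.3)^2)
  bufss <- 1 / (1 + 0.4 * 2.5e-4 / (cass + 2.5e-4)^2)

  list(c(
    -Itot,
    gate(m, minf, mtau), gate(h, hinf, 1 / (ah + bh)),
    gate(j, jinf, 1 / (aj + bj)),
    gate(xr1, xr1inf, xr1tau), gate(xr2, xr2inf, xr2tau),
    gate(xs, xsinf, xstau), gate(r, rinf, rtau), gate(s, sinf, stau),
    gate(d, dinf, dtau), gate(f, finf, ftau), gate(f2, f2inf, f2tau),
    gate(fcass, fcassinf, fcasstau),
    drbar,
    -(INa + IbNa + 3 * INaK + 3 * INaCa) * Cap / (Vc * Fd),
    -(IK1 + Ito + IKr + IKs - 2 * INaK + IpK + Istim) * Cap / (Vc * Fd),
    bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
              (IbCa + IpCa - 2 * INaCa) * Cap / (2 * Vc * Fd)),
    bufss * (-Ixfer * Vc / Vss + Irel * Vsr / Vss -
               ICaL * Cap / (2 * Vss * Fd)),
    bufsr * (Iup - Irel - Ileak)))
}

# note the oracle state order matches the package order except cai/cass
# (17, 18) which are cai then cass here as well -- identical ordering.
oracle_integrate <- function(y0, t_end, stim = function(t) 0) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  out <- deSolve::lsoda(unname(y0), seq(0, t_end, by = 1), tp06_rhs_oracle,
                        parms = list(stim = stim),
                        rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
  stats::setNames(out[nrow(out), -1], names(y0))
}

# analytic steady-state gain of a causal first-order Butterworth section
butter1_gain <- function(f, fc, type = c("low", "high")) {
  type <- match.arg(type)
  if (type == "low") 1 / sqrt(1 + (f / fc)^2)
  else (f / fc) / sqrt(1 + (f / fc)^2)
}

# amplitude of a steady-state sinusoid (fit of the trailing cycles)
sine_amplitude <- function(x, f, fs, cycles = 5) {
  n <- length(x)
  per <- fs / f
  idx <- seq(max(1, n - round(cycles * per)), n)
  tt <- (idx - 1) / fs
  fit <- stats::lm(x[idx] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# small healthy-tissue fixture with a catheter, cheap enough for the
# elliptic and electrogram unit tests
mini_config <- function(h = 0.4) {
  egmsim_config(
    grid = grid_spec(tissue_dims = c(24, 8, 2.4), blood_above = 8,
                     blood_below = 1.6, h = h),
    catheter = catheter_spec(shaft_length = 0),
    t_end = 40)
}

mini_domain <- function(orientation = "O", h = 0.4) {
  cfg <- mini_config(h)
  pose <- if (orientation == "O") pose(90, 0, 1.2) else pose(0, 30, 0)
  build_domain(cfg$grid, cfg$catheter, pose)
}
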
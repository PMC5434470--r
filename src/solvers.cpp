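#include <Rcpp.h>
#include "tp06.h"
using namespace Rcpp;

// Structured 7-point finite-volume operators on a voxel grid.
// A field x is stored Fortran-style: v = (k*ny + j)*nx + i.
// Face arrays hold one coupling per interior face:
//   gx: (nx-1) x ny x nz, gy: nx x (ny-1) x nz, gz: nx x ny x (nz-1).
// The operator is A x = diag .* x - sum_faces g * x_nbr with
// diag = sum of incident face couplings: symmetric positive semidefinite
// with nullspace = constants (homogeneous Neumann everywhere).

static inline int IDX(int i, int j, int k, int nx, int ny) {
  return (k * ny + j) * nx + i;
}

static void stencil_apply(const double *gx, const double *gy, const double *gz,
                          const double *x, double *y, int nx, int ny, int nz,
                          double scale, double shift) {
  // y = shift*x + scale*A x, with A as above (diag built on the fly)
  const int n = nx * ny * nz;
  for (int v = 0; v < n; v++) y[v] = shift * x[v];
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      const int row = (k * ny + j) * (nx - 1);
      for (int i = 0; i < nx - 1; i++) {
        const int a = IDX(i, j, k, nx, ny), b = a + 1;
        const double g = scale * gx[row + i], d = g * (x[a] - x[b]);
        y[a] += d; y[b] -= d;
      }
    }
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny - 1; j++) {
      const int row = (k * (ny - 1) + j) * nx;
      for (int i = 0; i < nx; i++) {
        const int a = IDX(i, j, k, nx, ny), b = a + nx;
        const double g = scale * gy[row + i], d = g * (x[a] - x[b]);
        y[a] += d; y[b] -= d;
      }
    }
  const int nxy = nx * ny;
  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny; j++) {
      const int row = (k * ny + j) * nx;
      for (int i = 0; i < nx; i++) {
        const int a = IDX(i, j, k, nx, ny), b = a + nxy;
        const double g = scale * gz[row + i], d = g * (x[a] - x[b]);
        y[a] += d; y[b] -= d;
      }
    }
}

static void stencil_diag(const double *gx, const double *gy, const double *gz,
                         double *dg, int nx, int ny, int nz,
                         double scale, double shift) {
  const int n = nx * ny * nz;
  for (int v = 0; v < n; v++) dg[v] = shift;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx - 1; i++) {
        const double g = scale * gx[(k * ny + j) * (nx - 1) + i];
        dg[IDX(i, j, k, nx, ny)] += g;
        dg[IDX(i + 1, j, k, nx, ny)] += g;
      }
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx; i++) {
        const double g = scale * gy[(k * (ny - 1) + j) * nx + i];
        dg[IDX(i, j, k, nx, ny)] += g;
        dg[IDX(i, j + 1, k, nx, ny)] += g;
      }
  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const double g = scale * gz[(k * ny + j) * nx + i];
        dg[IDX(i, j, k, nx, ny)] += g;
        dg[IDX(i, j, k + 1, nx, ny)] += g;
      }
}

// [[Rcpp::export]]
NumericVector cpp_stencil_apply(IntegerVector dims, NumericVector gx,
                                NumericVector gy, NumericVector gz,
                                NumericVector x) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector y(nx * ny * nz);
  stencil_apply(REAL(gx), REAL(gy), REAL(gz), REAL(x), REAL(y),
                nx, ny, nz, 1.0, 0.0);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_stencil_diag(IntegerVector dims, NumericVector gx,
                               NumericVector gy, NumericVector gz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector d(nx * ny * nz);
  stencil_diag(REAL(gx), REAL(gy), REAL(gz), REAL(d), nx, ny, nz, 1.0, 0.0);
  return d;
}

// Jacobi-preconditioned conjugate gradients for the singular pure-Neumann
// operator.  Constants are deflated: the right-hand side, the iterates and
// the preconditioned residual are kept orthogonal to the constant vector,
// which restores a well-posed problem on the zero-mean subspace.
// [[Rcpp::export]]
List cpp_pcg_neumann(IntegerVector dims, NumericVector gx, NumericVector gy,
                     NumericVector gz, NumericVector b, double tol,
                     int maxit, NumericVector x0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> dg(n), x(n, 0.0), r(n), z(n), p(n), Ap(n);
  stencil_diag(REAL(gx), REAL(gy), REAL(gz), dg.data(), nx, ny, nz, 1.0, 0.0);
  for (int v = 0; v < n; v++)
    if (dg[v] <= 0.0) stop("operator has a non-positive diagonal entry");

  double mean = 0.0;
  for (int v = 0; v < n; v++) mean += b[v];
  mean /= n;
  for (int v = 0; v < n; v++) r[v] = b[v] - mean;
  double bn = 0.0;
  for (int v = 0; v < n; v++) bn += r[v] * r[v];
  bn = std::sqrt(bn);
  if (bn == 0.0)
    return List::create(_["x"] = NumericVector(n), _["iters"] = 0,
                        _["relres"] = 0.0);
  if (x0.size() == n) {
    std::copy(x0.begin(), x0.end(), x.begin());
    stencil_apply(REAL(gx), REAL(gy), REAL(gz), x.data(), Ap.data(),
                  nx, ny, nz, 1.0, 0.0);
    for (int v = 0; v < n; v++) r[v] -= Ap[v];
  }

  auto precond = [&](const std::vector<double> &rr, std::vector<double> &zz) {
    double zm = 0.0;
    for (int v = 0; v < n; v++) { zz[v] = rr[v] / dg[v]; zm += zz[v]; }
    zm /= n;
    for (int v = 0; v < n; v++) zz[v] -= zm;
  };

  precond(r, z);
  std::copy(z.begin(), z.end(), p.begin());
  double rz = 0.0;
  for (int v = 0; v < n; v++) rz += r[v] * z[v];
  double rn = bn;
  int it;
  for (it = 0; it < maxit; it++) {
    stencil_apply(REAL(gx), REAL(gy), REAL(gz), p.data(), Ap.data(),
                  nx, ny, nz, 1.0, 0.0);
    double pAp = 0.0;
    for (int v = 0; v < n; v++) pAp += p[v] * Ap[v];
    if (pAp <= 0.0) break;
    const double al = rz / pAp;
    for (int v = 0; v < n; v++) { x[v] += al * p[v]; r[v] -= al * Ap[v]; }
    rn = 0.0;
    for (int v = 0; v < n; v++) rn += r[v] * r[v];
    rn = std::sqrt(rn);
    if (rn < tol * bn) { it++; break; }
    precond(r, z);
    double rz2 = 0.0;
    for (int v = 0; v < n; v++) rz2 += r[v] * z[v];
    const double bt = rz2 / rz;
    rz = rz2;
    for (int v = 0; v < n; v++) p[v] = z[v] + bt * p[v];
  }
  double xm = 0.0;
  for (int v = 0; v < n; v++) xm += x[v];
  xm /= n;
  NumericVector out(n);
  for (int v = 0; v < n; v++) out[v] = x[v] - xm;
  return List::create(_["x"] = out, _["iters"] = it, _["relres"] = rn / bn);
}

// ---------------------------------------------------------------------------
// Monodomain reaction-diffusion driver.
//
// Operator splitting per PDE step of length dt_pde:
//   1. n_sub Rush-Larsen/forward-Euler membrane substeps (dt_ode),
//      with voltage-dependent rates linearly interpolated from lookup
//      tables built for this dt_ode;
//   2. implicit-Euler diffusion solve (I + dt_pde K) V+ = V via
//      Jacobi-preconditioned CG warm-started at V.
// Face couplings gx/gy/gz are diffusion rates D_face/h^2 in 1/ms; faces to
// non-excitable voxels carry zero coupling (no-flux).
// ---------------------------------------------------------------------------

struct Tp06Lut {
  // one interleaved row per voltage sample:
  //   [0..10]  gate steady states (m h j xr1 xr2 xs r s d f f2)
  //   [11..21] gate Rush-Larsen factors exp(-dt/tau)
  //   [22..27] ical c1, ical c2, inak factor, naca1, naca2, ipk factor
  static const int N = 4001;
  static const int ROW = 28;
  double vmin, vmax, dv, inv_dv;
  std::vector<double> row;
  // inward-rectifier fraction tabulated in (V - EK)
  static const int NK = 5001;
  double kmin, kmax, dk, inv_dk;
  std::vector<double> xk1;

  void build(double dt) {
    vmin = -100.0; vmax = 100.0;
    dv = (vmax - vmin) / (N - 1); inv_dv = 1.0 / dv;
    row.assign((size_t)N * ROW, 0.0);
    using namespace tp06;
    for (int t = 0; t < N; t++) {
      const double V = vmin + t * dv;
      GateVals g[11] = {gate_m(V), gate_h(V), gate_j(V), gate_xr1(V),
                        gate_xr2(V), gate_xs(V), gate_r(V), gate_s(V),
                        gate_d(V), gate_f(V), gate_f2(V)};
      double *p = &row[(size_t)t * ROW];
      for (int q = 0; q < 11; q++) {
        p[q] = g[q].inf;
        p[11 + q] = std::exp(-dt / g[q].tau);
      }
      double a, b;
      ical_coefs(V, a, b);
      p[22] = a; p[23] = b;
      p[24] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * invRTF) +
                     0.0353 * std::exp(-V * invRTF));
      const double ea = std::exp(gamma_naca * V * invRTF);
      const double eb = std::exp((gamma_naca - 1.0) * V * invRTF);
      const double den = (KmNai * KmNai * KmNai + Nao * Nao * Nao) *
                         (KmCa + Cao) * (1.0 + ksat * eb);
      p[25] = kNaCa * Cao * ea / den;
      p[26] = kNaCa * Nao * Nao * Nao * alpha_naca * eb / den;
      p[27] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
    }
    kmin = -60.0; kmax = 220.0;
    dk = (kmax - kmin) / (NK - 1); inv_dk = 1.0 / dk;
    xk1.resize(NK);
    for (int t = 0; t < NK; t++) {
      const double u = kmin + t * dk;  // u = V - EK
      const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (u - 200.0)));
      const double bK1 = (3.0 * std::exp(0.0002 * (u + 100.0)) +
                          std::exp(0.1 * (u - 10.0))) /
                         (1.0 + std::exp(-0.5 * u));
      xk1[t] = aK1 / (aK1 + bK1);
    }
  }
  // interpolate the full row at V into out[ROW]
  inline void at_row(double V, double *out) const {
    double s = (V - vmin) * inv_dv;
    if (!(s >= 0.0)) s = 0.0;
    if (s > N - 1.001) s = N - 1.001;
    const int t = (int)s;
    const double w = s - t, cw = 1.0 - w;
    const double *p0 = &row[(size_t)t * ROW];
    const double *p1 = p0 + ROW;
    for (int k = 0; k < ROW; k++) out[k] = p0[k] * cw + p1[k] * w;
  }
  inline double atk(double u) const {
    double s = (u - kmin) * inv_dk;
    if (!(s >= 0.0)) s = 0.0;
    if (s > NK - 1.001) s = NK - 1.001;
    const int t = (int)s;
    const double w = s - t;
    return xk1[t] * (1.0 - w) + xk1[t + 1] * w;
  }
};

// [[Rcpp::export]]
List cpp_run_monodomain(IntegerVector dims, NumericVector gx, NumericVector gy,
                        NumericVector gz, LogicalVector excitable,
                        NumericMatrix state0, double dt_pde, int n_steps,
                        int n_sub, IntegerVector stim_cells, double stim_amp,
                        double stim_start, double stim_dur, NumericMatrix W,
                        IntegerVector probe_cells, IntegerVector snap_steps,
                        double cg_tol, int cg_maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (state0.nrow() != TP06_NSTATE || state0.ncol() != n)
    stop("state0 must be %d x n_voxels", TP06_NSTATE);
  const double dt_ode = dt_pde / n_sub;
  const int n_leads = W.ncol();
  if (n_leads > 0 && W.nrow() != n) stop("lead matrix must have n_voxels rows");

  Tp06Lut lut;
  lut.build(dt_ode);

  // cells actually integrated
  std::vector<int> cells;
  cells.reserve(n);
  for (int v = 0; v < n; v++) if (excitable[v]) cells.push_back(v);
  if (cells.empty()) stop("no excitable voxels");

  std::vector<double> S(state0.begin(), state0.end());  // 19 x n, col-major
  std::vector<double> stim_mask(n, 0.0);
  for (int q = 0; q < stim_cells.size(); q++) {
    const int v = stim_cells[q];
    if (v < 0 || v >= n) stop("stimulus voxel index out of range");
    stim_mask[v] = 1.0;
  }

  // implicit diffusion system M = I + dt_pde * A
  std::vector<double> Mdiag(n);
  stencil_diag(REAL(gx), REAL(gy), REAL(gz), Mdiag.data(), nx, ny, nz,
               dt_pde, 1.0);

  std::vector<double> V(n), rhsv(n), r(n), z(n), p(n), Ap(n);
  for (int v = 0; v < n; v++) V[v] = S[(size_t)v * TP06_NSTATE];

  NumericMatrix traces(n_steps + 1, n_leads);
  NumericMatrix probes(n_steps + 1, probe_cells.size());
  NumericMatrix snaps(snap_steps.size() > 0 ? n : 0, snap_steps.size());
  long cg_total = 0;

  auto record = [&](int step) {
    for (int l = 0; l < n_leads; l++) {
      double acc = 0.0;
      const double *w = &W(0, l);
      for (int v = 0; v < n; v++) acc += w[v] * V[v];
      traces(step, l) = acc;
    }
    for (int q = 0; q < probe_cells.size(); q++)
      probes(step, q) = V[probe_cells[q]];
    for (int q = 0; q < snap_steps.size(); q++)
      if (snap_steps[q] == step)
        for (int v = 0; v < n; v++) snaps(v, q) = V[v];
  };
  record(0);

  using namespace tp06;
  const double sqKo = std::sqrt(Ko / 5.4);

  for (int step = 0; step < n_steps; step++) {
    // --- membrane substeps ---
    for (size_t ci = 0; ci < cells.size(); ci++) {
      const int v = cells[ci];
      double *y = &S[(size_t)v * TP06_NSTATE];
      y[0] = V[v];
      // reversal potentials refreshed once per PDE step (concentrations
      // drift by < 1e-4 mM within 0.1 ms)
      const double EK = RTF * std::log(Ko / y[15]);
      const double ENa = RTF * std::log(Nao / y[14]);
      const double EKs = RTF * std::log((Ko + PKNa * Nao) /
                                        (y[15] + PKNa * y[14]));
      for (int sub = 0; sub < n_sub; sub++) {
        const double t = step * dt_pde + sub * dt_ode;
        const double stim =
            (stim_mask[v] != 0.0 && t >= stim_start && t < stim_start + stim_dur)
                ? stim_amp : 0.0;
        const double Vm = y[0];
        double L[Tp06Lut::ROW];
        lut.at_row(Vm, L);
        const double ECa = 0.5 * RTF * std::log(Cao / y[16]);

        const double INa = GNa * y[1] * y[1] * y[1] * y[2] * y[3] * (Vm - ENa);
        const double ICaL = GCaL * y[9] * y[10] * y[11] * y[12] *
                            (L[22] * y[17] - L[23]);
        const double Ito = Gto * y[7] * y[8] * (Vm - EK);
        const double IKr = GKr * sqKo * y[4] * y[5] * (Vm - EK);
        const double IKs = GKs * y[6] * y[6] * (Vm - EKs);
        const double IK1 = GK1 * sqKo * lut.atk(Vm - EK) * (Vm - EK);
        const double INaK = PNaK * Ko / (Ko + KmK) * y[14] / (y[14] + KmNa) *
                            L[24];
        const double INaCa = L[25] * y[14] * y[14] * y[14] - L[26] * y[16];
        const double IpCa = GpCa * y[16] / (y[16] + KpCa);
        const double IpK = GpK * L[27] * (Vm - EK);
        const double IbNa = GbNa * (Vm - ENa);
        const double IbCa = GbCa * (Vm - ECa);

        const double Itot = INa + ICaL + Ito + IKr + IKs + IK1 + INaK +
                            INaCa + IpCa + IpK + IbNa + IbCa - stim;

        // gates (Rush-Larsen via tables)
        for (int q = 0; q < 11; q++)
          y[1 + q] = L[q] + (y[1 + q] - L[q]) * L[11 + q];
        const GateVals gc = gate_fcass(y[17]);
        y[12] = gc.inf + (y[12] - gc.inf) * std::exp(-dt_ode / gc.tau);

        // CICR and concentrations (forward Euler)
        const double casr = y[18], cass = y[17], cai = y[16];
        const double kcasr =
            maxsr - (maxsr - minsr) / (1.0 + (EC / casr) * (EC / casr));
        const double k1 = k1p / kcasr, k2 = k2p * kcasr;
        y[13] += dt_ode * (-k2 * cass * y[13] + k4 * (1.0 - y[13]));
        const double Orel = k1 * cass * cass * y[13] /
                            (k3 + k1 * cass * cass);
        const double Irel = Vrel * Orel * (casr - cass);
        const double Ileak = Vleak * (casr - cai);
        const double Iup = Vmaxup / (1.0 + (Kup / cai) * (Kup / cai));
        const double Ixfer = Vxfer * (cass - cai);
        const double bufc =
            1.0 / (1.0 + Bufc * Kbufc / ((cai + Kbufc) * (cai + Kbufc)));
        const double bufsr =
            1.0 / (1.0 + Bufsr * Kbufsr / ((casr + Kbufsr) * (casr + Kbufsr)));
        const double bufss =
            1.0 / (1.0 + Bufss * Kbufss / ((cass + Kbufss) * (cass + Kbufss)));
        y[16] += dt_ode * bufc *
                 ((Ileak - Iup) * Vsr / Vc + Ixfer -
                  (IbCa + IpCa - 2.0 * INaCa) * Cap / (2.0 * Vc * Frdy));
        y[18] += dt_ode * bufsr * (Iup - Irel - Ileak);
        y[17] += dt_ode * bufss *
                 (-Ixfer * Vc / Vss + Irel * Vsr / Vss -
                  ICaL * Cap / (2.0 * Vss * Frdy));
        y[14] += dt_ode * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cap /
                           (Vc * Frdy));
        y[15] += dt_ode * (-(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK - stim) *
                           Cap / (Vc * Frdy));
        y[0] += dt_ode * (-Itot);
      }
      V[v] = y[0];
      if (!std::isfinite(y[0]))
        stop("numerical blow-up: Vm became non-finite at t = %.2f ms "
             "(reduce dt_pde / dt_ode)", (step + 1) * dt_pde);
    }

    // --- implicit diffusion: (I + dt A) V+ = V, warm start V ---
    std::copy(V.begin(), V.end(), rhsv.begin());
    stencil_apply(REAL(gx), REAL(gy), REAL(gz), V.data(), Ap.data(),
                  nx, ny, nz, dt_pde, 1.0);
    double bn = 0.0, rz = 0.0, rn0 = 0.0;
    for (int v = 0; v < n; v++) {
      r[v] = rhsv[v] - Ap[v];
      bn += rhsv[v] * rhsv[v];
      rn0 += r[v] * r[v];
    }
    bn = std::sqrt(bn);
    rn0 = std::sqrt(rn0);
    for (int v = 0; v < n; v++) { z[v] = r[v] / Mdiag[v]; rz += r[v] * z[v]; }
    std::copy(z.begin(), z.end(), p.begin());
    int it = 0;
    if (bn > 0.0 && rn0 > cg_tol * bn) {
      for (it = 0; it < cg_maxit; it++) {
        stencil_apply(REAL(gx), REAL(gy), REAL(gz), p.data(), Ap.data(),
                      nx, ny, nz, dt_pde, 1.0);
        double pAp = 0.0;
        for (int v = 0; v < n; v++) pAp += p[v] * Ap[v];
        if (pAp <= 0.0) break;
        const double al = rz / pAp;
        double rn = 0.0;
        for (int v = 0; v < n; v++) {
          V[v] += al * p[v];
          r[v] -= al * Ap[v];
          rn += r[v] * r[v];
        }
        if (std::sqrt(rn) < cg_tol * bn) { it++; break; }
        double rz2 = 0.0;
        for (int v = 0; v < n; v++) { z[v] = r[v] / Mdiag[v]; rz2 += r[v] * z[v]; }
        const double bt = rz2 / rz;
        rz = rz2;
        for (int v = 0; v < n; v++) p[v] = z[v] + bt * p[v];
      }
    }
    cg_total += it;

    record(step + 1);
    if ((step & 63) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix state_out(TP06_NSTATE, n);
  std::copy(S.begin(), S.end(), state_out.begin());
  // keep diffusion-updated V consistent in the returned state
  for (int v = 0; v < n; v++) state_out(0, v) = V[v];

  return List::create(_["traces"] = traces, _["probes"] = probes,
                      _["snapshots"] = snaps, _["state"] = state_out,
                      _["cg_iters"] = (double)cg_total);
}
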
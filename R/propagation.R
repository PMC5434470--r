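# Monodomain reaction-diffusion propagation on the excitable voxels.

#' Tissue-level monodomain parameters
#'
#' Surface-to-volume ratio and membrane capacitance enter the monodomain
#' equation beta*Cm dVm/dt = div(sigma_m grad Vm) - beta*Iion. The
#' dimensionless `d_scale` rescales the resulting diffusivity; its default
#' is calibrated once so that the reference strand protocol
#' ([measure_strand_cv()]) conducts at 800 mm/s with healthy-myocardium
#' conductivities (sigma_i = 0.40, sigma_e = 0.264 S/m), mirroring the
#' conduction-velocity calibration of the underlying model. See the
#' methods vignette for the rationale.
#'
#' @param beta Surface-to-volume ratio, 1/mm.
#' @param Cm Specific membrane capacitance, uF/cm^2.
#' @param d_scale Dimensionless diffusivity calibration factor.
#' @param dt_ode Membrane-model substep, ms.
#' @param dt_pde Diffusion step and electrogram sampling step, ms
#'   (0.1 ms = 10 kHz); must be an integer multiple of `dt_ode`.
#' @param cg_tol,cg_maxit Tolerance/iteration cap of the implicit
#'   diffusion solve.
#' @return A `tissue_params` object.
#' @export
tissue_params <- function(beta = 100, Cm = 0.1, d_scale = cv_d_scale(),
                          dt_ode = 0.02, dt_pde = 0.1,
                          cg_tol = 1e-10, cg_maxit = 400) {
  n_sub <- dt_pde / dt_ode
  stopifnot(beta > 0, Cm > 0, d_scale > 0,
            abs(n_sub - round(n_sub)) < 1e-9)
  structure(list(beta = beta, Cm = Cm, d_scale = d_scale, dt_ode = dt_ode,
                 dt_pde = dt_pde, n_sub = as.integer(round(n_sub)),
                 cg_tol = cg_tol, cg_maxit = cg_maxit),
            class = "tissue_params")
}

#' Calibrated diffusivity scale
#'
#' The frozen calibration constant of the monodomain diffusivity (see
#' [tissue_params()]). Recompute with [calibrate_cv_scale()].
#'
#' @return A single number.
#' @export
cv_d_scale <- function() 0.1115958

#' Monodomain diffusivity from conductivity
#'
#' Converts an effective conductivity (S/m) into the voxel diffusion
#' coefficient D = d_scale * sigma_m / (beta * Cm) in mm^2/ms, with beta in
#' 1/mm and Cm in uF/cm^2. A factor-of-100 slip in this conversion would
#' silently rescale all conduction velocities, so it is centralized here:
#' sigma/(beta*Cm) in SI units (S/m) / ((1/m) * (F/m^2)) = m^2/s, and
#' 1 m^2/s = 1000 mm^2/ms, giving D = 100 * sigma_m / (beta * Cm).
#'
#' @param sigma_m Effective conductivity, S/m.
#' @param params A [tissue_params()].
#' @return Diffusivity in mm^2/ms.
#' @export
monodomain_diffusivity <- function(sigma_m, params = tissue_params()) {
  params$d_scale * 100 * sigma_m / (params$beta * params$Cm)
}

#' Planar stimulus specification
#'
#' Stimulus currents applied in a strip at the left tissue boundary to
#' launch a planar wavefront.
#'
#' @param amplitude Stimulus current, uA/uF; the default is twice the
#'   diastolic threshold of the 2 ms tissue stimulus measured on the
#'   reference strand.
#' @param duration Stimulus duration, ms.
#' @param start Onset time, ms.
#' @param depth Strip depth from the left (x = 0) boundary, mm.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(amplitude = 2 * 14.26, duration = 2, start = 0.5,
                          depth = 1.5) {
  stopifnot(amplitude > 0, duration > 0, depth > 0, start >= 0)
  structure(list(amplitude = amplitude, duration = duration, start = start,
                 depth = depth), class = "stimulus_spec")
}

# Extract the tissue sub-box (full x/y extent, tissue z layers) of a
# labeled grid and build the face diffusion couplings D_face / h^2 with
# harmonic averaging; faces touching non-excitable voxels carry zero
# coupling (no-flux).
tissue_system <- function(grid, params) {
  kt <- grid$k_tissue
  dims <- c(grid$dims[1], grid$dims[2], length(kt))
  ex <- grid$excitable[, , kt, drop = FALSE]
  si <- grid$sigma_i[, , kt, drop = FALSE]
  se <- grid$sigma_e[, , kt, drop = FALSE]
  sm <- effective_conductivity(si, se)
  D <- monodomain_diffusivity(sm, params)
  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  h2 <- grid$h^2
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  gx <- harm(D[-nx, , , drop = FALSE], D[-1, , , drop = FALSE]) / h2
  gy <- harm(D[, -ny, , drop = FALSE], D[, -1, , drop = FALSE]) / h2
  gz <- harm(D[, , -nz, drop = FALSE], D[, , -1, drop = FALSE]) / h2
  list(dims = dims, gx = as.vector(gx), gy = as.vector(gy),
       gz = as.vector(gz), excitable = as.vector(ex),
       k_offset = kt[1] - 1L, n = prod(dims))
}

# voxel index (1-based, within the tissue box) of a point in mm
tissue_voxel_index <- function(sys, grid, p) {
  h <- grid$h
  ijk <- pmin(pmax(ceiling(c(p[1], p[2], p[3] - sys$k_offset * h) / h), 1),
              sys$dims)
  as.integer(((ijk[3] - 1) * sys$dims[2] + (ijk[2] - 1)) * sys$dims[1] +
               ijk[1])
}

#' Run a monodomain propagation simulation
#'
#' Integrates beta*Cm dVm/dt = div(sigma_m grad Vm) - beta*Iion + stimulus
#' on the excitable voxels of a labeled grid with no-flux boundaries,
#' using operator splitting: Rush-Larsen membrane substeps and
#' unconditionally stable implicit-Euler diffusion. Vm is sampled every
#' `dt_pde` (0.1 ms = 10 kHz by default).
#'
#' @param grid A `labeled_grid` from [build_domain()].
#' @param params A [tissue_params()].
#' @param stim A [stimulus_spec()].
#' @param t_end Simulation end time, ms.
#' @param probes List of points (mm) at which to record Vm.
#' @param snapshot_times Times (ms) at which to store the full Vm field.
#' @param leads Optional matrix of lead-field weight columns over the
#'   tissue box (see [lead_vector()]); electrogram samples are accumulated
#'   during time stepping.
#' @param state0 Optional initial state matrix (19 x n_voxels).
#' @return A `transmembrane_field` object with sampled probe traces,
#'   snapshots, lead traces and timing metadata.
#' @export
run_propagation <- function(grid, params = tissue_params(),
                            stim = stimulus_spec(), t_end = 60,
                            probes = NULL, snapshot_times = NULL,
                            leads = NULL, state0 = NULL) {
  stopifnot(inherits(grid, "labeled_grid"))
  sys <- tissue_system(grid, params)
  n_steps <- as.integer(round(t_end / params$dt_pde))
  if (!any(sys$excitable)) {
    # nothing can activate: Vm stays at rest everywhere
    rest <- init_resting_state()[["V"]]
    t <- seq(0, by = params$dt_pde, length.out = n_steps + 1)
    return(structure(
      list(t = t, sample_rate_khz = 1 / params$dt_pde,
           probes = matrix(rest, n_steps + 1, length(probes)),
           probe_points = probes, snapshots = NULL,
           snapshot_times = snapshot_times,
           lead_traces = matrix(0, n_steps + 1,
                                if (is.null(leads)) 0 else ncol(leads)),
           state = NULL, sys = sys, params = params,
           grid_dims = grid$dims, h = grid$h, k_offset = sys$k_offset,
           cg_iters = 0),
      class = "transmembrane_field"))
  }

  xs <- axis_centers(sys$dims[1], grid$h)
  stim_x <- which(xs <= stim$depth)
  stim_mask <- array(FALSE, sys$dims)
  stim_mask[stim_x, , ] <- TRUE
  stim_cells <- which(as.vector(stim_mask) & sys$excitable) - 1L
  if (!length(stim_cells)) stop("stimulus strip contains no excitable voxels")

  if (is.null(state0)) {
    rest <- init_resting_state()
    state0 <- matrix(rest, nrow = length(rest), ncol = sys$n)
  }
  probe_idx <- if (length(probes))
    vapply(probes, function(p) tissue_voxel_index(sys, grid, p),
           integer(1)) - 1L
  else integer(0)
  snap_steps <- if (length(snapshot_times))
    as.integer(round(snapshot_times / params$dt_pde)) else integer(0)
  W <- if (is.null(leads)) matrix(0, sys$n, 0) else leads
  stopifnot(nrow(W) == sys$n)

  out <- cpp_run_monodomain(sys$dims, sys$gx, sys$gy, sys$gz,
                            sys$excitable, state0, params$dt_pde, n_steps,
                            params$n_sub, stim_cells, stim$amplitude,
                            stim$start, stim$duration, W, probe_idx,
                            snap_steps, params$cg_tol, params$cg_maxit)
  t <- seq(0, by = params$dt_pde, length.out = n_steps + 1)
  structure(
    list(t = t, sample_rate_khz = 1 / params$dt_pde,
         probes = out$probes, probe_points = probes,
         snapshots = out$snapshots, snapshot_times = snapshot_times,
         lead_traces = out$traces, state = out$state,
         sys = sys, params = params, grid_dims = grid$dims, h = grid$h,
         k_offset = sys$k_offset, cg_iters = out$cg_iters),
    class = "transmembrane_field")
}

#' @export
print.transmembrane_field <- function(x, ...) {
  cat("<transmembrane_field> ", paste(x$sys$dims, collapse = " x "),
      " tissue voxels, ", length(x$t), " samples at ",
      x$sample_rate_khz, " kHz\n", sep = "")
  invisible(x)
}

# activation time: time of maximum temporal derivative of Vm
activation_time <- function(t, v) {
  dv <- diff(v) / diff(t)
  if (max(v) < -20 || max(dv) < 1) return(NA_real_)
  t[which.max(dv)]
}

#' Measure conduction velocity between two probes
#'
#' CV = distance / (activation-time difference), with activation defined
#' as the instant of maximum dVm/dt at each probe. Returns 0 (with
#' attribute `propagated = FALSE`) if either probe never activates.
#'
#' @param field A `transmembrane_field` with at least two recorded probes.
#' @param i1,i2 Probe indices (default first and second).
#' @return Conduction velocity in mm/s.
#' @export
measure_cv <- function(field, i1 = 1, i2 = 2) {
  stopifnot(inherits(field, "transmembrane_field"),
            ncol(field$probes) >= max(i1, i2))
  t1 <- activation_time(field$t, field$probes[, i1])
  t2 <- activation_time(field$t, field$probes[, i2])
  if (is.na(t1) || is.na(t2) || t2 == t1) {
    out <- 0
    attr(out, "propagated") <- FALSE
    return(out)
  }
  p1 <- field$probe_points[[i1]]; p2 <- field$probe_points[[i2]]
  d <- sqrt(sum((p2 - p1)^2))
  out <- 1000 * d / abs(t2 - t1)
  attr(out, "propagated") <- TRUE
  out
}

#' Conduction velocity on the reference strand
#'
#' The standard CV measurement protocol: a thin strand (one voxel cross
#' section, exactly planar propagation), planar stimulus at the left end,
#' probes at 30% and 70% of the strand length, activation from maximum
#' dVm/dt. Used both for the healthy-CV calibration and for the
#' border-zone conductivity sweep.
#'
#' @param sigma_i,sigma_e Conductivities, S/m.
#' @param h Voxel size, mm (use 0.05 or finer for slow conduction).
#' @param length Strand length, mm.
#' @param t_end Simulation time, ms (allow the wave to reach the far
#'   probe).
#' @param params A [tissue_params()]; its conductivity-independent entries
#'   are reused.
#' @param stim A [stimulus_spec()].
#' @return CV in mm/s (0 if no propagation).
#' @export
measure_strand_cv <- function(sigma_i = 0.40, sigma_e = 0.264, h = 0.1,
                              length = 40, t_end = 80,
                              params = tissue_params(),
                              stim = stimulus_spec()) {
  gs <- grid_spec(tissue_dims = c(length, h, h), blood_above = 0,
                  blood_below = 0, h = h)
  g <- build_domain(gs)
  g$sigma_i[g$excitable] <- sigma_i
  g$sigma_e[g$excitable] <- sigma_e
  p1 <- c(0.3 * length, h / 2, h / 2)
  p2 <- c(0.7 * length, h / 2, h / 2)
  f <- run_propagation(g, params, stim, t_end = t_end,
                       probes = list(p1, p2))
  measure_cv(f)
}

#' Recalibrate the diffusivity scale
#'
#' Bisects `d_scale` so that the reference strand protocol yields a target
#' conduction velocity (800 mm/s) with healthy-myocardium conductivities.
#' The shipped default ([cv_d_scale()]) was produced by this routine.
#'
#' @param target_cv Target CV, mm/s.
#' @param tol Relative CV tolerance.
#' @param ... Passed to [measure_strand_cv()].
#' @return The calibrated `d_scale`.
#' @export
calibrate_cv_scale <- function(target_cv = 800, tol = 1e-3, ...) {
  f <- function(s) measure_strand_cv(params = tissue_params(d_scale = s),
                                     ...) - target_cv
  lo <- 0.02; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) stop("bracket failure in CV calibration")
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    fm <- f(mid)
    if (abs(fm) < tol * target_cv) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  mid
}
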
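---
title: "Models and numerics behind egmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind egmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

egmsim is a forward model of the intracardiac electrograms recorded by an
8 mm nonirrigated radiofrequency (RF) ablation catheter that carries three
1 mm mini electrodes (MEs) embedded in its distal tip electrode. The
scientific question it serves is a practical one in ablation therapy:
when do the MEs tell the operator something the big tip electrode cannot
— about lesion maturity, lesion geometry, or conduction gaps in a linear
lesion? The package answers this by simulating electrical activation in a
slab of ventricular myocardium, computing the extracellular potential
field around the catheter, and extracting clinically filtered unipolar
and bipolar electrogram features over a set of mapping scenarios.

This vignette documents the models, their assumptions, the numerical
choices, and the limitations; it is the place where design decisions that
were genuinely open are recorded.

## Domain and geometry

The simulation domain is a rectangular box: an isotropic myocardial slab
(80 x 24 x 4.8 mm at full scale) immersed in blood (24.6 mm above,
6.6 mm below). The planar excitation wavefront travels along +x. The
domain is discretized into cubic voxels of edge `h`; every voxel carries
exactly one material label (tissue, necrotic lesion core, thermal border
zone, blood, distal electrode, ME1–3, insulation, shaft) with
intracellular/extracellular conductivities from the material table:
myocardium 0.40 / 0.264 S/m, blood 0.7 S/m, necrotic core 0.10 S/m
(extracellular only), electrodes 7000 S/m, insulation 1e-10 S/m.

The catheter is a capsule — a hemispherical tip plus a cylinder of
diameter 2.7 mm (8F), distal electrode length 8 mm — continued by an
insulated shaft. The three MEs are 1 mm discs on the lateral surface,
centered 2 mm from the tip, 120 degrees apart in the cross-section. The
frame convention fixes rotation zero so that ME1 sits at 90 degrees to
the propagation direction in the orthogonal pose, and ME2 faces the
tissue at rotation 30 degrees in the parallel pose; with that convention
ME1 and ME3 are exact mirror images across the propagation plane in the
parallel pose at rotation 30, which is why their tilt-sweep responses
coincide identically. The tilt axis lies in the x–z plane with the tip
pointing toward the arriving wavefront.

Penetration is defined as the signed depth of the deepest catheter
surface point below the tissue surface; the catheter *carves* the tissue
(voxels it occupies become catheter material) rather than deforming it
elastically — the deformation model is not specified by any data we
could anchor it to, and carving preserves the displaced-volume geometry
that matters for the field solution.

Two open geometry questions were decided as follows. The shaft is a
short insulating cylinder (default 10 mm at full scale, 4 mm in the
reduced configuration so that tilted poses fit the smaller blood pool).
The ME insulation thickness is nowhere specified; it is certainly much
thinner than a voxel, which motivates the sub-voxel treatment described
under *Extracellular solver*.

## Lesion model

Point lesions are truncated cones ("cone-like") with the axis normal to
the surface, spanning the full 4.8 mm wall (transmural), with surface
width equal to `width_depth_ratio * depth` (1.25 orthogonal, 1.6
parallel) or an explicit width (13 mm for the matured lesion). The
bottom radius is half the top radius; a full cone would taper to a point
at the far wall and let excitation sneak beneath a "transmural" line,
which contradicts the intended block.

An acute lesion consists of the unexcitable necrotic core plus a 3 mm
thermal border zone. The border temperature follows
`T(d) = 37 + 13 exp(-d / lambda)` with `lambda = 3 / ln(13/3) = 2.046 mm`,
which is the unique single-exponential profile through the two anchor
points T(0) = 50 C and T(3 mm) = 40 C; it continues smoothly toward
37 C beyond the border zone. Border intracellular conductivity is
log-linearly interpolated through the knots (37, 0.40), (40, 0.47),
(43, 0.53), (46, 0.36), (50, 0.01) S/m — conduction first speeds up with
mild hyperthermia, then collapses. The matured lesion ("necrotic only")
and the linear lesion carry no border zone; the linear lesion sweeps the
point profile across the slab, interrupted by an excitable conduction
gap (default width 1.5 mm).

## Membrane model and propagation

Membrane dynamics are the ten Tusscher–Panfilov (2006) human ventricular
model, epicardial parameter set (19 states). The variant and cell type
are a decision: the publication chain behind the tissue parameters uses
the 2006 model, and the slab is ventricular-like. Integration is
operator-split: Rush–Larsen exponential updates for the twelve
voltage-gated variables (tabulated vs. voltage at the run's `dt_ode`),
forward Euler for voltage, calcium subsystem and concentrations, at
`dt_ode = 0.02 ms`; diffusion advances by unconditionally stable
implicit Euler at `dt_pde = 0.1 ms` (also the 10 kHz electrogram
sampling interval) solved by Jacobi-preconditioned conjugate gradients,
warm-started, on a matrix-free 7-point stencil with face-harmonic
averaging of the effective conductivity.

The resting state shipped with the package is the model's true quiescent
fixed point (all derivatives below 1e-6 per ms), obtained by 1000 s of
unstimulated integration; the quiescent model drifts for minutes (mainly
intracellular Na+) before settling near -86.9 mV, so short relaxations
do not qualify as steady states.

Propagation solves the monodomain reduction — exact for the isotropic,
equal-ratio setting used here — with effective conductivity
`sigma_m = sigma_i * sigma_e / (sigma_i + sigma_e)` and no-flux
boundaries at blood and domain edges. Bath loading of the surface
conduction velocity is therefore neglected.

### Conduction-velocity calibration

The tissue parameters state beta = 100 /mm and Cm = 0.1 uF/cm^2. Taken
literally with sigma_m = 0.159 S/m these give a monodomain diffusivity
of 1.59 mm^2/ms and a planar conduction velocity (CV) near 2100 mm/s —
far from the 800 mm/s the conductivities were tuned to deliver in the
original calibration. The parameter triple is internally inconsistent
under any standard monodomain scaling, so egmsim performs the same
calibration the source model performed: a dimensionless diffusivity
factor `d_scale` (frozen at 0.1116, reproducible with
`calibrate_cv_scale()`) is fixed once so that the *reference strand
protocol* — a 40 mm strand of one-voxel cross section at h = 0.1 mm,
2 ms twice-diastolic-threshold stimulus, activation times from maximum
dVm/dt at 30% and 70% of the strand — conducts at exactly 800 mm/s with
healthy conductivities. The equivalent effective beta*Cm is about
900 F/m^3, i.e. the textbook Cm of roughly 0.9–1 uF/cm^2 at
beta = 100 /mm. Planar propagation in an isotropic no-flux strand is
exactly independent of the cross-section, so the one-voxel strand is a
symmetry reduction, not an approximation. Everything downstream of the
calibration is a prediction: the warm border endpoint (sigma_i = 0.36)
conducts at 784 mm/s, and sqrt-scaling holds across the conductivity
table. At the hottest border value (sigma_i = 0.01 S/m, h = 0.05 mm
strand) the model conducts at ~194 mm/s; cable theory pins this number
at 800 * sqrt(sigma_m(0.01)/sigma_m(0.40)) = 197 mm/s, so values
substantially below that (as sometimes quoted for graded lesion borders)
can only arise from loading by adjacent unexcitable tissue, not from a
homogeneous strand.

The default stimulus (28.5 uA/uF, 2 ms, 1.5 mm strip at the left
boundary) is twice the measured diastolic threshold of that protocol.

## Extracellular solver and electrograms

At each sampling instant the extracellular potential solves the
quasi-static elliptic problem
`div((sigma_i + sigma_e) grad phi_e) = -div(sigma_i grad Vm)` over the
whole box with homogeneous Neumann boundaries and the zero-mean
uniqueness constraint (the integral of phi_e over the domain vanishes).
The operator is a symmetric positive-semidefinite 7-point stencil with
face-harmonic conductivities; the constraint is enforced by deflating
constants out of the right-hand side and the CG iterates (tolerance
1e-9). No algebraic multigrid is used: with deflated Jacobi-PCG a
200k–1.5M voxel solve converges in a few hundred iterations, and only a
handful of solves are needed per pose, as follows.

Unipolar electrograms are the mean potential over an electrode's voxels
minus the mean over the top 1 mm blood layer (the reference; catheter
voxels are excluded since they are not blood). Because the problem is
linear and the operator is constant in time, each referenced electrogram
is, by reciprocity, a fixed linear functional of Vm: one adjoint solve
per electrode and pose yields a lead-field weight vector, after which
every 10 kHz sample is a dot product accumulated during time stepping.
This is exact up to solver tolerance (verified in the tests against
explicit per-instant solves) and replaces hundreds of elliptic solves
per pose with four. Bipolar electrograms subtract two unfiltered
unipolar traces. Filtering is causal first-order Butterworth, high-pass
then low-pass: 0.5–250 Hz for unipolar, 30–350 Hz for bipolar; the
unipolar filter type and order are a decision (clinical systems filter
causally, and the stated bipolar filter style is first-order
Butterworth). Features are the positive/negative peaks, their
difference Vpp, and the local activation time defined as the steepest
downstroke between the maximum and minimum peaks of the filtered trace.

### The mini-electrode insulation aperture

The MEs are insulated from the surrounding distal metal by a film that
is far thinner than any affordable voxel. If the insulation is
voxelized literally, the aperture in the metal shield around each ME
grows by a voxel of insulator on every side, the ME sees too much of
the unshielded field, and ME-vs-distal electrogram differences inflate
by factors of 2–3. egmsim therefore discretizes the insulation as a
sub-voxel film: the collar voxels are filled with electrode metal in
the operator, and the ME–collar faces carry zero conductance. The
stored per-voxel conductivity of insulation voxels remains 1e-10 S/m.
With this scheme the healthy orthogonal ME1–ME2 bipolar amplitude
converges to the few-mV scale expected for a 1 mm aperture, while
removing the insulation in a test fixture correctly shorts the MEs to
the distal electrode.

## Scenarios

Seven scenarios drive the pipeline end to end, each returning a tidy
feature table (one row per sweep value, electrode and trace kind) with
reference-normalized Vpp columns: healthy myocardium (orthogonal:
tilt 90, penetration 1.2 mm; parallel: gentle contact, rotation 30),
tilt sweep (90 to 0 degrees in 15-degree steps, 0.6 mm tip–surface gap
at 90 degrees shrinking linearly to contact at 0, referenced to the
90-degree pose), rotation sweep (referenced to each electrode's
minimum), penetration sweep (1.2 to 0 mm orthogonal, 0.6 to -0.6 mm
parallel, referenced to the initial pose), acute lesion with border
zone (pre/post pairs), matured necrotic-core movement (shifts referenced
to the central position), and the linear lesion with a conduction gap
(shifts along the line, referenced to the gap position). Poses that
share identical excitable tissue (e.g. all rotations of a
penetration-free parallel catheter) share one propagation run; only the
lead fields are recomputed per pose. The pipeline contains no random
number generation anywhere, so identical configurations reproduce
bitwise-identical tables.

## Problem sizes and what the reduced runs show

The package's default ("scaled") configuration is a 40 x 16 x 4.8 mm
slab with 13 / 3.2 mm blood layers at h = 0.3 mm — about 0.5M voxels in
the field solve and 115k tissue voxels — with a 4 mm shaft. At this
scale one pose costs well under a minute on one core, a full tilt sweep
a few minutes. The acceptance script runs all scenario quantities at
this single resolution. The full-size
configuration (`egmsim_config("paper")`, also shipped as a YAML file in
`inst/extdata`) reproduces the complete 80 x 24 mm setup and runs for
hours per scenario.

Relative Vpp effects — the orderings between electrodes, the sharp ME
response when crossing a lesion border, the gap signature — are robust
across h = 0.45 to 0.2 (asserted by the resolution-robustness tests).
Absolute amplitudes of the *difference* signals (bipolar ME-vs-distal)
and the near-field quantities of a tissue-contacting ME converge more
slowly, because they hinge on a 1 mm aperture and a tangent-contact
patch measured in single voxels at coarse h; the remaining
deviations of the scaled runs from the full-size reference values are
dominated by exactly these terms (quantified in the repository's test
suite rather than restated here).

## Limitations

The slab is isotropic (no fiber anisotropy), flat, and stationary; bath
loading on CV is neglected by the monodomain reduction; the RF delivery
itself is not simulated (lesions are prescribed geometrically); there is
no edema, no fibrosis, no mechanoelectric coupling, no
electrode–electrolyte interface, and no measurement noise. Electrograms
from a contracting, trabeculated atrium will differ in absolute
amplitude; the package's claims concern relative changes across poses
and lesion states under controlled geometry.
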
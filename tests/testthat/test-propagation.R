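# Monodomain solver: effective conductivity, planar propagation,
# conduction-velocity scaling and block.

test_that("effective conductivity is the harmonic combination", {
  expect_equal(effective_conductivity(0.40, 0.264), 0.40 * 0.264 / 0.664)
  expect_equal(round(effective_conductivity(0.40, 0.264), 4), 0.1590)
  expect_equal(effective_conductivity(0, 0.264), 0)
  s <- 0.37
  expect_equal(effective_conductivity(s, s), s / 2)
})

test_that("diffusivity unit conversion is exact", {
  # sigma/(beta*Cm): (S/m) / ((1/mm)*(uF/cm^2)) -> mm^2/ms carries a
  # factor 100; a slip here would rescale every conduction velocity
  p <- tissue_params(beta = 100, Cm = 0.1, d_scale = 1)
  expect_equal(monodomain_diffusivity(0.159, p), 100 * 0.159 / 10)
})

test_that("a fully unexcitable domain stays at rest", {
  cfg <- mini_config()
  g <- build_domain(cfg$grid)
  g$excitable[] <- FALSE
  g$sigma_i[] <- 0
  f <- run_propagation(g, t_end = 2, probes = list(c(5, 1, 2)))
  expect_equal(as.vector(f$probes),
               rep(init_resting_state()[["V"]], length(f$t)))
})

test_that("planar stimulation keeps isochrones planar", {
  gs <- grid_spec(tissue_dims = c(20, 6, 2.4), blood_above = 0,
                  blood_below = 0, h = 0.3)
  g <- build_domain(gs)
  pts <- list(c(14, 1, 0.4), c(14, 3, 1.2), c(14, 5, 2.0),
              c(14, 2, 2.2), c(14, 4, 0.2), c(14, 5.8, 1.2))
  f <- run_propagation(g, t_end = 40, probes = pts)
  at <- apply(f$probes, 2, function(v) egmsim:::activation_time(f$t, v))
  expect_true(all(is.finite(at)))
  expect_lt(diff(range(at)), 1)
  expect_lt(stats::sd(at), 0.5)
})

test_that("CV is monotone in the effective conductivity", {
  sig <- c(0.01, 0.05, 0.15, 0.40, 0.53)
  cv <- vapply(sig, function(s)
    measure_strand_cv(sigma_i = s, h = 0.1, length = 30, t_end = 300),
    numeric(1))
  expect_true(all(diff(cv) > 0))
  expect_true(all(cv > 0))
})

test_that("CV scales as the square root of the diffusivity", {
  cv1 <- measure_strand_cv(length = 30, t_end = 60)
  cv2 <- measure_strand_cv(length = 30, t_end = 60,
                           params = tissue_params(d_scale = 2 * cv_d_scale()))
  expect_lt(abs(cv2 / cv1 - sqrt(2)), 0.05 * sqrt(2))
})

test_that("CV converges under grid refinement", {
  cva <- measure_strand_cv(h = 0.15, length = 30, t_end = 60)
  cvb <- measure_strand_cv(h = 0.10, length = 30, t_end = 60)
  expect_lt(abs(cva - cvb) / cvb, 0.05)
})

test_that("probes that never activate give the no-propagation sentinel", {
  gs <- grid_spec(tissue_dims = c(12, 0.3, 0.3), blood_above = 0,
                  blood_below = 0, h = 0.3)
  g <- build_domain(gs)
  # kill excitability beyond x = 6 mm
  xs <- axis_centers(g$dims[1], g$h)
  g$excitable[xs > 6, , g$k_tissue] <- FALSE
  g$sigma_i[!g$excitable] <- 0
  f <- run_propagation(g, t_end = 20,
                       probes = list(c(3, .15, .15), c(10, .15, .15)))
  cv <- measure_cv(f)
  expect_equal(as.numeric(cv), 0)
  expect_false(attr(cv, "propagated"))
})

test_that("a gap-free transmural line blocks conduction; a gap conducts", {
  gs <- grid_spec(tissue_dims = c(24, 8, 2.4), blood_above = 0,
                  blood_below = 0, h = 0.3)
  block <- build_domain(gs, lesion = lesion_spec(
    "linear_with_gap", necrotic_width = 6, gap_width = 0, taper = 1))
  pr <- list(c(4, 4, 1.2), c(20, 4, 1.2))
  f1 <- run_propagation(block, t_end = 60, probes = pr)
  cv1 <- measure_cv(f1)
  expect_false(attr(cv1, "propagated"))
  expect_lt(max(f1$probes[, 2]), -60)   # distal side never activates

  gap <- build_domain(gs, lesion = lesion_spec(
    "linear_with_gap", necrotic_width = 6, gap_width = 1.5, taper = 1))
  f2 <- run_propagation(gap, t_end = 60, probes = pr)
  expect_true(attr(measure_cv(f2), "propagated"))
  expect_gt(max(f2$probes[, 2]), 0)
})

test_that("identical configurations give bitwise-identical results", {
  f1 <- measure_strand_cv(length = 20, t_end = 40)
  f2 <- measure_strand_cv(length = 20, t_end = 40)
  expect_identical(f1, f2)
})
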
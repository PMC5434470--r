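# Elliptic extracellular solver: operator structure, uniqueness
# constraint, dipole oracle, electrode equipotentiality, lead fields.

test_that("operator annihilates constants, is symmetric, conserves", {
  g <- mini_domain("O")
  op <- assemble_operator(g)
  n <- prod(op$dims)
  expect_equal(max(abs(apply_operator(op, rep(1, n)))), 0)
  expect_equal(max(abs(apply_operator(op, rep(2.5, n), "intra"))), 0)

  skip_if_not_installed("Matrix")
  gs <- grid_spec(tissue_dims = c(3, 2, 1.2), blood_above = 1.2,
                  blood_below = 0.6, h = 0.6)
  gsm <- build_domain(gs)
  ops <- assemble_operator(gsm)
  A <- operator_matrix(ops)
  expect_equal(max(abs(A - Matrix::t(A))), 0)
  expect_equal(max(abs(Matrix::rowSums(A))), 0)
  # matrix route agrees with the matrix-free stencil
  x <- sin(seq_len(nrow(A)))
  expect_equal(as.numeric(A %*% x), apply_operator(ops, x),
               tolerance = 1e-12)
})

test_that("assembly rejects non-positive conductivity", {
  g <- mini_domain("O")
  g$sigma_e[1, 1, 1] <- 0
  g$sigma_i[1, 1, 1] <- 0
  expect_error(assemble_operator(g), "positive")
})

test_that("uniform Vm produces no extracellular field", {
  g <- mini_domain("O")
  op <- assemble_operator(g)
  nt <- prod(c(g$dims[1:2], length(g$k_tissue)))
  ph <- solve_phie(op, g, rep(-40, nt))
  expect_lt(max(abs(ph$phi)), 1e-10)
})

test_that("point-current dipole matches the analytic potential", {
  # uniform-conductivity box, +/- unit current at two voxels 4 apart;
  # compare with the superposed point-source potentials of an unbounded
  # conductor at 3-8 voxel distances (box large enough that the Neumann
  # walls perturb the field by well under the tolerance)
  N <- 61L; ctr <- 31L
  n <- rep(N, 3)
  one <- array(1, n)
  gx <- as.vector(one[-N, , ]); gy <- as.vector(one[, -N, ])
  gz <- as.vector(one[, , -N])
  b <- array(0, n)
  src <- c(ctr, ctr, ctr - 2L); snk <- c(ctr, ctr, ctr + 2L)
  b[src[1], src[2], src[3]] <- 1
  b[snk[1], snk[2], snk[3]] <- -1
  sol <- egmsim:::cpp_pcg_neumann(n, gx, gy, gz, as.vector(b), 1e-10,
                                  20000, numeric(0))
  phi <- array(sol$x, n)
  analytic <- function(p) {
    rp <- sqrt(sum((p - src)^2)); rm <- sqrt(sum((p - snk)^2))
    (1 / rp - 1 / rm) / (4 * pi)
  }
  pts <- rbind(c(ctr, ctr, ctr - 6L), c(ctr, ctr, ctr + 6L),
               c(ctr + 1L, ctr + 1L, ctr - 7L), c(ctr + 2L, ctr, ctr - 3L),
               c(ctr, ctr + 2L, ctr + 3L))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    a <- analytic(p)
    expect_lt(abs(phi[p[1], p[2], p[3]] - a) / abs(a), 0.05)
  }
})

test_that("solved fields satisfy the zero-integral uniqueness constraint", {
  g <- mini_domain("O")
  op <- assemble_operator(g)
  f <- run_propagation(g, t_end = 16, snapshot_times = c(14))
  ph <- solve_phie(op, g, f$snapshots[, 1])
  expect_lt(abs(mean(ph$phi)),
            1e-8 * sqrt(mean(ph$phi^2)))
  expect_lt(ph$relres, 1e-8)
})

test_that("electrodes are equipotential during wave passage", {
  g <- mini_domain("O")
  op <- assemble_operator(g)
  f <- run_propagation(g, t_end = 16, snapshot_times = c(14))
  ph <- solve_phie(op, g, f$snapshots[, 1])
  vpp_global <- diff(range(ph$phi))
  expect_lt(electrode_equipotentiality(ph, g, "electrode_distal"),
            0.01 * vpp_global)
  expect_lt(electrode_equipotentiality(ph, g, "electrode_me1"),
            0.01 * vpp_global)
  # single-voxel electrode: spread is exactly zero
  g1 <- g
  w <- which(g1$label == egm_labels()[["blood"]])[1]
  g1$label[w] <- egm_labels()[["electrode_me2"]]
  g1$label[g1$label == egm_labels()[["electrode_me2"]] &
             seq_along(g1$label) != w] <- egm_labels()[["blood"]]
  expect_equal(electrode_equipotentiality(ph, g1, "electrode_me2"), 0)
})

test_that("removing the insulation shorts the MEs to the distal electrode", {
  g <- mini_domain("O")
  labs <- egm_labels()
  g$label[g$label == labs[["isolation"]]] <- labs[["electrode_distal"]]
  g$sigma_e[g$label == labs[["electrode_distal"]]] <- 7000
  op <- assemble_operator(g)
  f <- run_propagation(g, t_end = 16, snapshot_times = c(14))
  ph <- solve_phie(op, g, f$snapshots[, 1])
  wD <- egmsim:::label_weights(g, "electrode_distal")
  w1 <- egmsim:::label_weights(g, "electrode_me1")
  phD <- sum(as.vector(ph$phi) * wD)
  ph1 <- sum(as.vector(ph$phi) * w1)
  expect_lt(abs(phD - ph1), 0.01 * diff(range(ph$phi)))
  sprd <- electrode_equipotentiality(ph, g, "electrode_me1")
  expect_lt(sprd, 0.01 * diff(range(ph$phi)))
})

test_that("phi_e decays monotonically into the blood pool", {
  g <- mini_domain("O")
  # remove the catheter influence: plain slab + bath
  cfg <- mini_config()
  g <- build_domain(cfg$grid)
  op <- assemble_operator(g)
  f <- run_propagation(g, t_end = 14, snapshot_times = c(12))
  ph <- solve_phie(op, g, f$snapshots[, 1])
  # |phi| averaged over x-y at 5 heights above the tissue surface
  k0 <- max(g$k_tissue)
  amp <- vapply(1:5, function(q)
    max(abs(ph$phi[, , k0 + 3 * q])), numeric(1))
  expect_true(all(diff(amp) < 0))
})

test_that("raising blood conductivity damps blood-pool potentials", {
  cfg <- mini_config()
  g <- build_domain(cfg$grid)
  f <- run_propagation(g, t_end = 14, snapshot_times = c(12))
  g2 <- g
  g2$sigma_e[g2$label == egm_labels()[["blood"]]] <- 1.4
  ph1 <- solve_phie(assemble_operator(g), g, f$snapshots[, 1])
  ph2 <- solve_phie(assemble_operator(g2), g2, f$snapshots[, 1])
  k_blood <- max(g$k_tissue) + 5
  expect_lt(max(abs(ph2$phi[, , k_blood])), max(abs(ph1$phi[, , k_blood])))
})

test_that("lead-field traces equal explicit per-sample solves", {
  g <- mini_domain("O")
  op <- assemble_operator(g)
  lv <- lead_vector(op, g, "electrode_distal")
  times <- c(8, 12, 16)
  f <- run_propagation(g, t_end = 20, snapshot_times = times,
                       leads = cbind(lv$w))
  explicit <- vapply(seq_along(times), function(q) {
    ph <- solve_phie(op, g, f$snapshots[, q])
    wE <- egmsim:::label_weights(g, "electrode_distal")
    wR <- egmsim:::reference_weights(g)
    sum(as.vector(ph$phi) * (wE - wR))
  }, numeric(1))
  direct <- f$lead_traces[round(times / 0.1) + 1, 1]
  expect_equal(direct, explicit, tolerance = 1e-4)
})
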
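# Domain builder: voxel counts, catheter pose, mini-electrode layout,
# lesion geometry and the thermal border-zone model.

test_that("voxel counts follow the slab and bath dimensions", {
  gs <- grid_spec(tissue_dims = c(80, 24, 4.8), blood_above = 24.6,
                  blood_below = 6.6, h = 0.4)
  expect_identical(gs$n_tissue, c(200L, 60L, 12L))
  expect_identical(gs$dims[3], as.integer(round(36 / 0.4)))
  g <- build_domain(gs)
  expect_equal(sum(g$label == egm_labels()[["tissue"]]), 200 * 60 * 12)
})

test_that("labels partition the domain for every pose/lesion combination", {
  cfg <- mini_config()
  combos <- list(
    list(pose(90, 0, 1.2), lesion_spec("none")),
    list(pose(0, 30, 0), lesion_spec("point_with_border", depth = 2.4)),
    list(pose(45, 120, -0.3),
         lesion_spec("point_necrotic_only", necrotic_width = 5)),
    list(pose(0, 200, 0.2), lesion_spec("linear_with_gap", necrotic_width = 4)))
  for (cb in combos) {
    g <- build_domain(cfg$grid, cfg$catheter, cb[[1]], cb[[2]])
    expect_identical(sum(table(g$label)), length(g$label))
    expect_true(all(g$label %in% egm_labels()))
    # conductivity invariants
    expect_true(all(g$sigma_i[!g$excitable] == 0))
    labs <- egm_labels()
    expect_true(all(g$sigma_e[g$label == labs[["electrode_distal"]]] == 7000))
    expect_true(all(g$sigma_e[g$label == labs[["isolation"]]] == 1e-10))
    expect_true(all(g$sigma_e[g$label == labs[["blood"]]] == 0.7))
  }
})

test_that("orthogonal pose: tip penetrates 1.2 mm, MEs sit in blood", {
  g <- mini_domain("O")
  labs <- egm_labels()
  zs <- axis_centers(g$dims[3], g$h)
  cath <- array(g$label %in% labs[5:10], g$dims)
  # deepest catheter voxel center is about 1.2 mm below the surface
  z_min <- min(zs[apply(cath, 3, any)])
  expect_lt(abs((g$z_surface - 1.2) - (z_min - g$h / 2)), g$h)
  # every ME voxel lies above the tissue surface (blood region)
  for (lb in c("electrode_me1", "electrode_me2", "electrode_me3")) {
    me <- which(array(g$label == labs[[lb]], g$dims), arr.ind = TRUE)
    expect_gt(nrow(me), 0)
    expect_true(all(zs[me[, 3]] > g$z_surface))
  }
})

face_adjacent_to <- function(g, lab_a, lab_b) {
  labs <- egm_labels()
  A <- array(g$label == labs[[lab_a]], g$dims)
  B <- array(g$label == labs[[lab_b]], g$dims)
  shift <- function(m, d, ax) {
    out <- array(FALSE, dim(m))
    n <- dim(m)[ax]
    idx <- lapply(dim(m), seq_len)
    src <- idx; src[[ax]] <- seq_len(n - abs(d)) + max(0, -d)
    dst <- idx; dst[[ax]] <- seq_len(n - abs(d)) + max(0, d)
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  nb <- shift(B, 1, 1) | shift(B, -1, 1) | shift(B, 1, 2) |
    shift(B, -1, 2) | shift(B, 1, 3) | shift(B, -1, 3)
  any(A & nb)
}

test_that("parallel pose at rotation 30: only ME2 touches the tissue", {
  g <- mini_domain("P")
  expect_true(face_adjacent_to(g, "electrode_me2", "tissue"))
  expect_false(face_adjacent_to(g, "electrode_me1", "tissue"))
  expect_false(face_adjacent_to(g, "electrode_me3", "tissue"))
})

test_that("ME centers: 120 degree spacing, periodicity, wavefront angle", {
  cath <- catheter_spec()
  p0 <- pose(90, 0, 1.2)
  c1 <- me_center(cath, p0, 1)
  expect_equal(c1, me_center(cath, pose(90, 360, 1.2), 1))
  # azimuths in the cross-sectional (x, y) plane for the orthogonal pose
  ctr <- egmsim:::catheter_c0(grid_spec(), cath, p0)
  az <- sapply(1:3, function(k) {
    v <- me_center(cath, p0, k) - ctr
    atan2(v[2], v[1]) * 180 / pi
  })
  sep <- sort((az - az[1]) %% 360)
  expect_equal(sep, c(0, 120, 240), tolerance = 1e-10)
  # ME1 is perpendicular to the propagation direction (+x)
  expect_equal(((az[1] - 90) %% 360), 0, tolerance = 1e-10)
})

test_that("rotating by 120 degrees permutes the ME voxel sets", {
  cfg <- mini_config()
  g0 <- build_domain(cfg$grid, cfg$catheter, pose(90, 0, 1.2))
  g1 <- build_domain(cfg$grid, cfg$catheter, pose(90, 120, 1.2))
  labs <- egm_labels()
  set <- function(g, lb) which(g$label == labs[[lb]])
  # +120 deg moves ME1 onto ME3's base azimuth, ME2 onto ME1's, ME3 onto ME2's
  expect_identical(set(g1, "electrode_me1"), set(g0, "electrode_me3"))
  expect_identical(set(g1, "electrode_me2"), set(g0, "electrode_me1"))
  expect_identical(set(g1, "electrode_me3"), set(g0, "electrode_me2"))
})

test_that("border-zone temperature profile has the stated endpoints", {
  les <- lesion_spec("point_with_border")
  expect_equal(lesion_temperature(les, 0), 50)
  expect_equal(lesion_temperature(les, 3), 40)
  # closed form: T(d) = 37 + 13 exp(-d / lambda), lambda = 3/log(13/3)
  lam <- 3 / log(13 / 3)
  d <- c(0.5, 1.023, 2, 2.9)
  expect_equal(lesion_temperature(les, d), 37 + 13 * exp(-d / lam))
  # monotone nonincreasing, continuous at the border edge
  dd <- seq(0, 6, by = 0.01)
  Tv <- lesion_temperature(les, dd)
  expect_true(all(diff(Tv) <= 0))
  expect_lt(abs(lesion_temperature(les, 3 - 1e-12) -
                  lesion_temperature(les, 3 + 1e-12)), 1e-9)
  # lesions without border zone are at body temperature
  expect_equal(lesion_temperature(lesion_spec("point_necrotic_only",
                                              necrotic_width = 5), d),
               rep(37, length(d)))
})

test_that("border-zone conductivity interpolates the published ranges", {
  expect_equal(sigma_i_of_temperature(c(37, 40, 43, 46, 50)),
               c(0.40, 0.47, 0.53, 0.36, 0.01))
  expect_equal(sigma_i_of_temperature(55), 0.01)  # clamped
  expect_equal(sigma_i_of_temperature(20), 0.40)
})

test_that("point lesion geometry: width, border, transmurality", {
  cfg <- egmsim_config()
  # necrotic-only, width 13 mm: surface width of the necrotic label
  g <- build_domain(cfg$grid, lesion =
                      lesion_spec("point_necrotic_only", necrotic_width = 13))
  labs <- egm_labels()
  top <- g$label[, , max(g$k_tissue)]
  xs <- axis_centers(g$dims[1], g$h)
  nec_x <- range(xs[apply(top == labs[["lesion_necrotic"]], 1, any)])
  expect_lt(abs(diff(nec_x) + g$h - 13), 2 * g$h)
  expect_false(any(g$label == labs[["lesion_border"]]))
  # transmural: necrotic present in bottom tissue layer
  expect_true(any(g$label[, , min(g$k_tissue)] == labs[["lesion_necrotic"]]))

  # acute lesion in O: width/depth 1.25, depth 4.8 -> 6 mm core width
  g2 <- build_domain(cfg$grid, lesion =
                       lesion_spec("point_with_border",
                                   width_depth_ratio = 1.25))
  top2 <- g2$label[, , max(g2$k_tissue)]
  nec_x2 <- range(xs[apply(top2 == labs[["lesion_necrotic"]], 1, any)])
  expect_lt(abs(diff(nec_x2) + g2$h - 6), 2 * g2$h)
  expect_true(any(g2$label == labs[["lesion_border"]]))
  # border sigma_i spans the heated range, sigma_e fixed at 0.264
  bz <- g2$label == labs[["lesion_border"]]
  expect_true(all(g2$sigma_e[bz] == 0.264))
  expect_true(all(g2$sigma_i[bz] >= 0.01 - 1e-9 &
                    g2$sigma_i[bz] <= 0.53 + 1e-9))
  expect_true(all(g2$temperature[bz] >= 40 - 1 & g2$temperature[bz] <= 50))
})

test_that("linear lesion leaves an excitable corridor of the gap width", {
  cfg <- egmsim_config()
  g <- build_domain(cfg$grid, lesion =
                      lesion_spec("linear_with_gap", necrotic_width = 13,
                                  gap_width = 1.5))
  labs <- egm_labels()
  # along the lesion line (x = center), excitable voxels form a corridor
  i0 <- round(dim(g$label)[1] / 2)
  mid <- g$excitable[i0, , g$k_tissue[1]]
  ys <- axis_centers(g$dims[2], g$h)
  corridor <- range(ys[mid])
  expect_lt(abs(diff(corridor) + g$h - 1.5), 2 * g$h)
  # corridor is centered on the slab midline
  expect_lt(abs(mean(corridor) - g$dims[2] * g$h / 2), g$h)
})

test_that("geometry errors are raised", {
  cfg <- mini_config()
  expect_error(build_domain(cfg$grid, cfg$catheter,
                            pose(90, 0, 1.2, translation_mm = c(100, 0))),
               "outside")
  expect_error(build_domain(cfg$grid, catheter_spec(shaft_length = 50),
                            pose(90, 0, 1.2)), "outside")
  gs6 <- grid_spec(tissue_dims = c(24, 8, 2.4), blood_above = 8,
                   blood_below = 1.6, h = 0.6)
  expect_error(build_domain(gs6, cfg$catheter, pose(90, 0, 1.2)),
               "resolve")
  expect_error(build_domain(cfg$grid, lesion =
                              lesion_spec("point_necrotic_only",
                                          necrotic_width = 50)),
               "wider")
})

test_that("voxelization converges: region volumes stable under refinement", {
  vol <- function(h) {
    g <- mini_domain("O", h = h)
    tab <- table(factor(g$label, levels = egm_labels(),
                        labels = names(egm_labels())))
    tab * h^3
  }
  v1 <- vol(0.3)
  v2 <- vol(0.15)
  for (lb in c("tissue", "blood", "electrode_distal", "shaft")) {
    if (v1[lb] > 0)
      expect_lt(abs(v2[lb] - v1[lb]) / v1[lb], 0.10)
  }
})
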
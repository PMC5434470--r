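# Scenario pipeline on a small fixture: determinism, morphology,
# result structure, exports and configuration.

cfg_mini <- mini_config()
res_mini <- run_healthy("O", cfg_mini)

test_that("healthy scenario produces the full electrode/kind table", {
  df <- tidy(res_mini)
  expect_s3_class(df, "tbl_df")
  expect_setequal(df$electrode[df$kind == "unipolar"],
                  c("D", "ME1", "ME2", "ME3"))
  expect_true(all(c("ME1-ME2", "D-ME1", "D-ME2") %in%
                    df$electrode[df$kind == "bipolar"]))
  expect_true(all(df$v_pp_mV > 0))
  expect_true(all(df$v_pp_mV == df$pos_peak_mV - df$neg_peak_mV))
  expect_true(all(abs(df$rel_vpp_pct - 100) < 1e-9))
})

test_that("unipolar electrograms have RS morphology over healthy tissue", {
  tr <- attr(res_mini, "traces")[[1]]
  for (e in c("D", "ME1", "ME2", "ME3")) {
    v <- tr[[e]]$samples
    expect_gt(max(v), 0)
    expect_lt(min(v), 0)
    expect_lt(which.max(v), which.min(v))  # positive peak first
    ft <- egm_features(tr[[e]])
    expect_true(ft$lat_defined)
  }
})

test_that("the pipeline is deterministic", {
  res2 <- run_healthy("O", cfg_mini)
  expect_identical(tidy(res_mini), tidy(res2))
})

test_that("LAT difference across electrodes matches distance over CV", {
  # two Vm probes 10 mm apart along the propagation axis
  g <- build_domain(cfg_mini$grid)
  f <- run_propagation(g, t_end = 40,
                       probes = list(c(6, 4, 1.2), c(16, 4, 1.2)))
  a1 <- egmsim:::activation_time(f$t, f$probes[, 1])
  a2 <- egmsim:::activation_time(f$t, f$probes[, 2])
  cv <- as.numeric(measure_cv(f))
  expect_equal(a2 - a1, 10 / cv * 1000, tolerance = 0.05 * (a2 - a1))
})

test_that("feature and trace CSV exports round-trip", {
  fcsv <- tempfile(fileext = ".csv")
  write_features_csv(res_mini, fcsv)
  back <- utils::read.csv(fcsv)
  expect_equal(nrow(back), nrow(res_mini))
  expect_true(all(c("electrode", "kind", "v_pp_mV", "lat_ms") %in%
                    names(back)))
  tcsv <- tempfile(fileext = ".csv")
  write_traces_csv(res_mini, tcsv)
  tb <- utils::read.csv(tcsv)
  expect_equal(tb$t_ms[2] - tb$t_ms[1], 0.1)
  expect_true(all(c("D", "ME1", "ME1.ME2") %in% names(tb)))
  unlink(c(fcsv, tcsv))
})

test_that("VTK export writes a well-formed legacy image file", {
  g <- mini_domain("O")
  vtk <- tempfile(fileext = ".vtk")
  write_vtk_image(g, vtk, fields = c("label", "sigma_e"))
  ln <- readLines(vtk, n = 10)
  expect_true(any(grepl("STRUCTURED_POINTS", ln)))
  expect_true(any(grepl(sprintf("DIMENSIONS %d %d %d", g$dims[1],
                                g$dims[2], g$dims[3]), ln)))
  expect_gt(file.size(vtk), 1000)
  unlink(vtk)
})

test_that("YAML configuration round-trips", {
  yml <- tempfile(fileext = ".yml")
  writeLines(c("scale: scaled",
               "grid:",
               "  tissue_dims: [24, 8, 2.4]",
               "  blood_above: 8",
               "  blood_below: 1.6",
               "  h: 0.4",
               "catheter:",
               "  shaft_length: 0",
               "t_end: 40",
               "sweeps:",
               "  tilt: [90, 45, 0]"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$grid$tissue_dims, c(24, 8, 2.4))
  expect_equal(cfg$catheter$shaft_length, 0)
  expect_equal(cfg$t_end, 40)
  expect_equal(cfg$sweeps$tilt, c(90, 45, 0))
  expect_equal(cfg$sweeps$linear_gap, seq(-4, 4, by = 1))  # default kept
  unlink(yml)
})

test_that("tidiers and autoplot methods work", {
  gl <- glance(res_mini)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$scenario, "healthy")
  p1 <- autoplot(res_mini)
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(attr(res_mini, "traces")[[1]]$D)
  expect_s3_class(p2, "ggplot")
  p3 <- autoplot(mini_domain("O"))
  expect_s3_class(p3, "ggplot")
})

test_that("run_scenario dispatches by name", {
  cfgp <- cfg_mini
  cfgp$sweeps$penetration_O <- c(1.2, 0.8)
  res <- run_scenario("penetration", "O", cfgp)
  expect_s3_class(res, "sweep_result")
  df <- tidy(res)
  expect_setequal(unique(df$parameter), c(1.2, 0.8))
  # reference convention: initial pose is 100%
  expect_true(all(abs(df$rel_vpp_pct[df$parameter == 1.2] - 100) < 1e-9))
})
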
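# Electrogram construction, filtering and feature extraction.

make_trace <- function(v, kind = "unipolar", fs = 10) {
  egmsim:::new_egm_trace(seq(0, by = 1 / fs, length.out = length(v)),
                         v, kind, "probe")
}

test_that("bipolar traces are antisymmetric differences", {
  t1 <- make_trace(sin(1:100))
  t2 <- make_trace(cos(1:100))
  expect_equal(bipolar_trace(t1, t1)$samples, rep(0, 100))
  expect_equal(bipolar_trace(t1, t2)$samples, -bipolar_trace(t2, t1)$samples)
  expect_error(bipolar_trace(t1, make_trace(sin(1:50))), "length")
  expect_error(bipolar_trace(filter_trace(t1), t2), "unfiltered")
})

test_that("filters reject DC and match the analytic Butterworth gains", {
  # constant input decays towards zero through the high-pass section
  const <- make_trace(rep(1, 5000), kind = "bipolar")
  out <- filter_trace(const)
  expect_lt(abs(out$samples[5000]), 1e-3)

  fs <- 10000
  tt <- seq(0, 1, by = 1 / fs)
  for (f0 in c(50, 100)) {
    tr <- make_trace(sin(2 * pi * f0 * tt), kind = "unipolar")
    ftr <- filter_trace(tr)
    gain <- sine_amplitude(ftr$samples, f0, fs)
    expected <- butter1_gain(f0, 0.5, "high") * butter1_gain(f0, 250, "low")
    expect_equal(gain, expected, tolerance = 0.01)
  }
  # bipolar chain: 500 Hz attenuated more than 100 Hz
  g100 <- sine_amplitude(filter_trace(
    make_trace(sin(2 * pi * 100 * tt), kind = "bipolar"))$samples, 100, fs)
  g500 <- sine_amplitude(filter_trace(
    make_trace(sin(2 * pi * 500 * tt), kind = "bipolar"))$samples, 500, fs)
  expect_lt(g500, g100)

  expect_error(filter_trace(filter_trace(const)), "already")
})

test_that("cascaded first-order sections commute", {
  set.seed(42)
  x <- make_trace(cumsum(rnorm(2000)))
  fs <- x$fs_khz * 1000
  hp <- signal::butter(1, 30 / (fs / 2), type = "high")
  lp <- signal::butter(1, 350 / (fs / 2), type = "low")
  a <- signal::filter(lp, signal::filter(hp, x$samples))
  b <- signal::filter(hp, signal::filter(lp, x$samples))
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("features of a single sine period are exact", {
  T <- 20  # ms
  tt <- seq(0, T, by = 0.1)
  tr <- make_trace(sin(2 * pi * tt / T))
  tr$filtered <- TRUE
  ft <- egm_features(tr)
  expect_equal(ft$v_pp_mV, 2, tolerance = 1e-3)
  expect_equal(ft$pos_peak_mV, 1, tolerance = 1e-3)
  expect_equal(ft$neg_peak_mV, -1, tolerance = 1e-3)
  # steepest descent at the midpoint
  expect_equal(ft$lat_ms, T / 2, tolerance = 0.1)
  expect_true(ft$lat_defined)

  # scaling: Vpp scales, LAT unchanged
  tr5 <- tr; tr5$samples <- 5 * tr$samples
  ft5 <- egm_features(tr5)
  expect_equal(ft5$v_pp_mV, 5 * ft$v_pp_mV)
  expect_equal(ft5$lat_ms, ft$lat_ms)

  # non-RS morphology (min before max): LAT undefined, Vpp kept
  trr <- tr; trr$samples <- -tr$samples
  ftr <- egm_features(trr)
  expect_false(ftr$lat_defined)
  expect_true(is.na(ftr$lat_ms))
  expect_equal(ftr$v_pp_mV, 2, tolerance = 1e-3)
})

test_that("filtering is linear: scaled sources scale Vpp exactly", {
  set.seed(7)
  raw <- cumsum(rnorm(800))
  f1 <- filter_trace(make_trace(raw))
  f2 <- filter_trace(make_trace(3 * raw))
  expect_equal(3 * egm_features(f1)$v_pp_mV, egm_features(f2)$v_pp_mV,
               tolerance = 1e-3 * egm_features(f2)$v_pp_mV)
})

test_that("relative Vpp conventions", {
  v <- c(4, 5, 8)
  expect_equal(relative_vpp(v, 1), c(100, 125, 200))
  expect_equal(relative_vpp(v, "min")[1], 100)
  expect_equal(relative_vpp(rep(3, 4), 2), rep(100, 4))
  expect_error(relative_vpp(c(0, 1), 1), "positive")
})

test_that("uniform fields give a zero unipolar trace", {
  g <- mini_domain("O")
  ph <- structure(list(phi = array(3.7, g$dims), dims = g$dims, h = g$h),
                  class = "extracellular_field")
  tr <- unipolar_trace(list(ph, ph), g, "electrode_distal", c(0, 0.1))
  expect_equal(tr$samples, c(0, 0))
})
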
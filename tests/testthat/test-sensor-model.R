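test_that("ITF is periodic in the FSR, bounded, and has the designed fringe width", {
  spec <- the_sensor()
  wl <- seq(1530, 1570, by = 0.01)
  r <- itf_reflectance(spec, wl)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(itf_reflectance(spec, wl), itf_reflectance(spec, wl + spec$fsr_nm),
               tolerance = 1e-12)
  # extremum at resonance: symmetric difference derivative vanishes
  eps <- 1e-6
  d0 <- (itf_reflectance(spec, spec$resonance_nm + eps) -
         itf_reflectance(spec, spec$resonance_nm - eps)) / (2 * eps)
  expect_lt(abs(d0), 1e-6)
  # fringe FWHM located by bisection on the modelled fringe
  rmin <- itf_reflectance(spec, spec$resonance_nm)
  half <- (1 + rmin) / 2
  up <- uniroot(function(l) itf_reflectance(spec, l) - half,
                c(spec$resonance_nm, spec$resonance_nm + spec$fsr_nm / 2),
                tol = 1e-10)$root
  lo <- uniroot(function(l) itf_reflectance(spec, l) - half,
                c(spec$resonance_nm - spec$fsr_nm / 2, spec$resonance_nm),
                tol = 1e-10)$root
  expect_equal(up - lo, spec$fsr_nm / spec$finesse, tolerance = 1e-6)
  expect_equal(up - lo, 0.347, tolerance = 0.01)   # 26.6 nm / 76.6
})

test_that("non-physical sensor specs are rejected", {
  expect_error(fp_sensor_spec(visibility = 1.2), "visibility")
  expect_error(fp_sensor_spec(finesse = 0.5), "finesse")
  expect_error(fp_sensor_spec(nep_mode_kpa = 0), "nep_mode")
})

test_that("optimum bias sits on the positive-slope flank and matches a brute-force grid", {
  set.seed(42)
  for (i in 1:20) {
    spec <- fp_sensor_spec(finesse = runif(1, 10, 120),
                           visibility = runif(1, 0.3, 1),
                           fsr_nm = runif(1, 15, 40),
                           resonance_nm = 1550)
    lb <- optimum_bias(spec)
    # brute force on a 1e-4 nm grid over the positive-slope half fringe
    grid <- seq(spec$resonance_nm, spec$resonance_nm + spec$fsr_nm / 2,
                by = 1e-4)
    sl <- fpscan:::itf_slope(spec, grid)
    expect_equal(lb, grid[which.max(sl)], tolerance = 2e-4)
    expect_gt(fpscan:::itf_slope(spec, lb), 0)       # positive slope by convention
    # strictly between the resonance minimum and the fringe half-maximum
    rmin <- itf_reflectance(spec, spec$resonance_nm)
    half_wl <- uniroot(function(l) itf_reflectance(spec, l) - (1 + rmin) / 2,
                       c(spec$resonance_nm, spec$resonance_nm + spec$fsr_nm / 2),
                       tol = 1e-10)$root
    expect_gt(lb, spec$resonance_nm)
    expect_lt(lb, half_wl + 1e-6)
  }
})

test_that("bias-parity: a 0.08 nm bias spread keeps sensitivity near 90% for the 0.35 nm fringe", {
  # fringe FWHM 0.35 nm as stated for the multibeam sensors
  spec <- fp_sensor_spec(finesse = 26.6 / 0.35, visibility = 0.78,
                         fsr_nm = 26.6)
  expect_equal(spec$fringe_fwhm_nm, 0.35, tolerance = 1e-12)
  ratio <- bias_sensitivity_ratio(spec, 0.08)
  expect_gte(ratio, 0.85)
  expect_lt(ratio, 1)
})

test_that("thickness tolerance is the printed bilinear relation", {
  expect_equal(thickness_tolerance(25, 1550, 0.08), 1.29, tolerance = 0.005)
  expect_lt(thickness_tolerance(25, 1550, 0.08), 1.3)
  expect_equal(thickness_tolerance(25, 1550, 0), 0)
  expect_equal(thickness_tolerance(50, 1550, 0.08),
               2 * thickness_tolerance(25, 1550, 0.08))
  expect_equal(thickness_tolerance(25, 3100, 0.08),
               thickness_tolerance(25, 1550, 0.08) / 2)
  expect_error(thickness_tolerance(25, 0, 0.08))
})

test_that("frequency response is unity in band, -3 dB at f3db, and monotone to the first null", {
  spec <- fp_sensor_spec(f3db_mhz = 35)
  expect_equal(frequency_response(spec, 0.1), 1, tolerance = 1e-3)
  expect_equal(frequency_response(spec, 35), 1 / sqrt(2), tolerance = 1e-9)
  f <- seq(0, 35, by = 0.5)
  expect_true(all(diff(frequency_response(spec, f)) <= 1e-12))
  expect_lt(frequency_response(spec, 70), frequency_response(spec, 35))
})

test_that("NEP maps reproduce the requested mode and FWHM and are reproducible", {
  m <- sample_nep_map(192, 180, 0.2, 0.25, seed = 1)
  expect_true(all(m > 0))
  expect_identical(m, sample_nep_map(192, 180, 0.2, 0.25, seed = 1))
  expect_false(identical(m, sample_nep_map(192, 180, 0.2, 0.25, seed = 2)))
  # histogram mode within 10%, FWHM within 15%
  dens <- density(m, n = 2048)
  mode_est <- dens$x[which.max(dens$y)]
  expect_lt(abs(mode_est - 0.2) / 0.2, 0.10)
  half <- max(dens$y) / 2
  above <- range(dens$x[dens$y >= half])
  expect_lt(abs(diff(above) - 0.25) / 0.25, 0.15)
})
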
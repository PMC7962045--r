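test_that("peak extraction recovers known synthetic peak heights", {
  # flat zero trace -> zero peak
  flat <- gen_cv_trace(0, baseline = c(0, 0), noise_sd = 0, seed = 1)
  expect_equal(as.numeric(suppressWarnings(extract_peak_current(flat))), 0,
               tolerance = 1e-15)
  # Gaussian peak of known height on a sloping baseline, window >= 6 widths
  for (conc in c(1e-3, 3e-3, 5e-3)) {
    tr <- gen_cv_trace(conc, noise_sd = 0, seed = 1)
    h <- 2e-3 * conc
    expect_equal(as.numeric(extract_peak_current(tr)), h, tolerance = 0.02)
  }
  # peaks increase with concentration in the linear regime
  p2 <- as.numeric(extract_peak_current(gen_cv_trace(2e-3, seed = 2)))
  p4 <- as.numeric(extract_peak_current(gen_cv_trace(4e-3, seed = 3)))
  expect_gt(p4, p2)
  expect_equal(p4 / p2, 2, tolerance = 0.05)
})

test_that("peak extraction is exactly invariant to added linear baselines", {
  tr <- gen_cv_trace(4e-3, seed = 5)
  tr2 <- tr
  tr2$current <- tr2$current + 3e-6 + 7e-6 * tr2$potential
  expect_equal(as.numeric(extract_peak_current(tr)),
               as.numeric(extract_peak_current(tr2)), tolerance = 1e-12)
})

test_that("peak extraction validates its window and flags edge maxima", {
  tr <- gen_cv_trace(4e-3, seed = 5)
  expect_error(extract_peak_current(tr, peak_potential = 1.5), "anodic")
  # monotone ramp in the window: maximum lands on the edge
  ramp <- gen_cv_trace(0, baseline = c(0, 0), noise_sd = 0, seed = 1)
  ramp$current <- exp(ramp$potential)   # convex: positive residual at edges
  expect_warning(pk <- extract_peak_current(ramp), "edge")
  expect_true(attr(pk, "edge"))
})

test_that("calibration fitting matches the sums oracle and flags plateaus", {
  pts <- data.frame(concentration = (0:6) * 1e-3, response = (0:6) * 2e-3)
  cal <- build_calibration(pts, fit_range = c(0, 6e-3))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  # all-zero responses: zero slope, r2 reported as 0
  z <- build_calibration(data.frame(concentration = (0:5) * 1e-3, response = 0))
  expect_equal(z$slope, 0)
  expect_equal(z$r_squared, 0)
  # plateau beyond 6 mM drags r2 down when fitted across it
  concs <- c(0:10) * 1e-3
  resp <- 2e-3 * pmin(concs, 6e-3)
  full <- build_calibration(data.frame(concentration = concs, response = resp),
                            fit_range = c(0, 10e-3))
  upto6 <- build_calibration(data.frame(concentration = concs, response = resp),
                             fit_range = c(0, 6e-3))
  expect_lt(full$r_squared, upto6$r_squared)
  expect_equal(upto6$slope, 2e-3 / 1e-3 * 1e-3, tolerance = 1e-12)
  orc <- ols_sums(concs[concs <= 6e-3], resp[concs <= 6e-3])
  expect_equal(upto6$slope, orc$slope, tolerance = 1e-12)
  expect_error(build_calibration(pts[1:2, ]), "3 calibration points")
})

test_that("linear-range detection finds the piecewise structure", {
  # fully linear data: one window spanning everything
  lin <- data.frame(concentration = (0:10) * 1e-3, response = (0:10) * 3)
  w <- detect_linear_range(lin, r2_min = 0.99)
  expect_identical(nrow(w), 1L)
  expect_equal(c(w$from, w$to), c(0, 10e-3))
  # linear to 6, plateau 6-10, linear 10-24: two windows at the printed ranges
  concs <- c(0:10, seq(12, 24, 2)) * 1e-3
  pts <- gen_cv_calibration(concs, seed = 11)
  w2 <- detect_linear_range(pts, r2_min = 0.99)
  expect_identical(nrow(w2), 2L)
  expect_equal(w2$to[1], 6e-3)
  expect_equal(c(w2$from[2], w2$to[2]), c(10e-3, 24e-3))
  # pure noise never qualifies at a strict threshold
  set.seed(99)
  noise <- data.frame(concentration = (0:11) * 1e-3, response = rnorm(12))
  expect_identical(nrow(detect_linear_range(noise, r2_min = 0.99)), 0L)
})

test_that("limit of detection follows the blank-noise formula", {
  expect_identical(limit_of_detection(0, 2e-3), 0)
  expect_equal(limit_of_detection(1e-8, 2e-3), 3.3 * 1e-8 / 2e-3)
  expect_equal(limit_of_detection(2e-8, 2e-3),
               2 * limit_of_detection(1e-8, 2e-3))               # linear in sigma
  expect_equal(limit_of_detection(1e-8 * 50, 2e-3 * 50),
               limit_of_detection(1e-8, 2e-3), tolerance = 1e-15) # unit rescaling
  expect_error(limit_of_detection(1e-8, 0), "slope")
})

test_that("blank replicates recover the generator noise level", {
  blanks <- gen_blank_traces(12, seed = 100)
  sdb <- estimate_blank_sd(blanks)
  expect_equal(sdb, 1e-8, tolerance = 0.5)   # right order, MC scatter allowed
  lod <- limit_of_detection(sdb, 2e-3)
  expect_equal(lod, 3.3 * 1e-8 / 2e-3, tolerance = 0.5)
})

test_that("area-normalised sensitivity and unit conversions are consistent", {
  expect_equal(sensitivity_per_area(21, 1), 21)
  expect_equal(sensitivity_per_area(21, 0.5), 42)
  expect_error(sensitivity_per_area(21, 0), "area")
  # 1 mM glucose = 18.016 mg/dL; 6 mM ~ 108 mg/dL; round trip to 4 sig figs
  expect_equal(glucose_mM_to_mgdl(6), 108.1, tolerance = 1e-3)
  for (x in c(0.1, 2.5, 6, 24))
    expect_equal(glucose_mgdl_to_mM(glucose_mM_to_mgdl(x)), x, tolerance = 1e-4)
})
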
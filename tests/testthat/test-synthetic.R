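test_that("generators are byte-identical under a fixed seed", {
  s1 <- gen_charge_force(30, seed = 5); s2 <- gen_charge_force(30, seed = 5)
  expect_identical(s1, s2)
  t1 <- gen_cv_trace(3e-3, seed = 5); t2 <- gen_cv_trace(3e-3, seed = 5)
  expect_identical(t1, t2)
  # and at the level of the stored decimal text output
  p1 <- tempfile(); p2 <- tempfile()
  write_xy_table(t1, p1); write_xy_table(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
  # different seeds differ
  expect_false(identical(gen_charge_force(30, seed = 6)$charge, s1$charge))
})

test_that("zero-noise charge series are exactly collinear", {
  s <- gen_charge_force(25, slope = 4.5, intercept = 0.3, noise_sd = 0, seed = 1)
  expect_equal(s$charge, 4.5 * s$force + 0.3, tolerance = 1e-14)
  expect_true(all(s$force >= 0 & s$force <= 4))
})

test_that("cv generator reproduces the programmed potential sweep", {
  tr <- gen_cv_trace(2e-3, seed = 3)
  expect_equal(max(tr$potential), 1.0, tolerance = 1e-9)
  expect_equal(min(tr$potential), -1.2, tolerance = 1e-9)
  expect_equal(tr$potential[1], 0.5)
  expect_equal(attr(tr, "scan_rate"), 0.1)
  expect_equal(attr(tr, "scans"), 4)
  # time axis consistent with the scan rate
  expect_equal(diff(tr$time)[1], 0.002 / 0.1, tolerance = 1e-12)
})

test_that("saturating response gives equal peaks on the 6-10 mM plateau", {
  p7 <- as.numeric(extract_peak_current(gen_cv_trace(7e-3, seed = 21)))
  p9 <- as.numeric(extract_peak_current(gen_cv_trace(9e-3, seed = 22)))
  h6 <- 2e-3 * 6e-3
  expect_equal(p7, p9, tolerance = 0.02)
  expect_equal(p7, h6, tolerance = 0.03)
  # blank trace: no peak above the noise floor
  b <- as.numeric(extract_peak_current(gen_cv_trace(0, seed = 23)))
  expect_lt(abs(b), 5e-8)
})

test_that("tissue perturbation preserves zeros and respects the fraction", {
  base <- tissue_materials()
  same <- perturb_tissue_params(base, 0, seed = 1)
  expect_equal(same, base, tolerance = 1e-15)
  for (seed in 1:5) {
    p <- perturb_tissue_params(base, 0.3, seed = seed)
    expect_identical(p$epidermis$perfusion, 0)       # zero stays exactly zero
    expect_identical(p$epidermis$metabolic_heat, 0)
    for (nm in names(base)) {
      expect_identical(p[[nm]]$blood_temperature, base[[nm]]$blood_temperature)
      for (f in c("density", "conductivity", "specific_heat")) {
        ratio <- p[[nm]][[f]] / base[[nm]][[f]]
        expect_true(ratio >= 0.7 && ratio <= 1.3,
                    info = sprintf("%s$%s seed %d", nm, f, seed))
      }
    }
  }
  expect_error(perturb_tissue_params(base, 0.9), "fraction")
})

test_that("generated files round-trip through the delimited-text readers", {
  s <- gen_charge_force(20, seed = 9)
  p <- tempfile(fileext = ".csv")
  write_xy_table(s, p)
  r <- read_xy_table(p)
  expect_equal(r$force, s$force, tolerance = 1e-12)
  expect_equal(r$charge, s$charge, tolerance = 1e-12)
  expect_equal(attr(r, "slope"), 4.5)
  fit <- fit_charge_force(r)
  expect_s3_class(fit, "charge_force_fit")
  tr <- gen_cv_trace(4e-3, seed = 9)
  pt <- tempfile(fileext = ".csv")
  write_xy_table(tr, pt)
  tr2 <- read_trace(pt)
  expect_s3_class(tr2, "cv_trace")
  expect_equal(as.numeric(extract_peak_current(tr2)),
               as.numeric(extract_peak_current(tr)), tolerance = 1e-9)
  unlink(c(p, pt))
})
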
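#' Generate a synthetic charge-force calibration series
#'
#' Emulates the quasi-static characterisation of the piezoelectric pressure
#' sensor: forces evenly spaced over the test range, charge equal to
#' `slope * force + intercept` plus i.i.d. Gaussian noise. Fully
#' reproducible under a fixed seed.
#'
#' @param n number of samples (>= 2).
#' @param slope true charge-force slope in pC/N (the generator's d33;
#'   default 4.5).
#' @param intercept baseline offset in pC.
#' @param noise_sd Gaussian noise standard deviation in pC (>= 0).
#' @param force_range force range in N (default 0-4).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return data.frame with columns `force` (N) and `charge` (pC);
#'   attributes record the generator parameters.
#' @examples
#' s <- gen_charge_force(50, seed = 1)
#' coef(fit_charge_force(s))
#' @export
gen_charge_force <- function(n = 50, slope = 4.5, intercept = 0,
                             noise_sd = 0.5, force_range = c(0, 4),
                             seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stopf("`n` must be >= 2")
  check_number(noise_sd, "noise_sd", lower = 0)
  force <- seq(force_range[1], force_range[2], length.out = n)
  charge <- with_seed(seed, slope * force + intercept + rnorm(n, 0, noise_sd))
  structure(data.frame(force = force, charge = charge),
            slope = slope, intercept = intercept, noise_sd = noise_sd,
            seed = seed)
}

# Piecewise-linear saturating response of the glucose generator, in
# "gain units": linear below the first breakpoint, flat between the
# breakpoints, linear again above (slope restored). Breakpoints default to
# 6 and 10 mM, mirroring the published linear ranges (up to 6 mM and
# 10-24 mM with a plateau in between).
saturating_response <- function(concentration, breaks = c(6e-3, 10e-3)) {
  c1 <- breaks[1]; c2 <- breaks[2]
  ifelse(concentration <= c1, concentration,
         ifelse(concentration <= c2, c1, c1 + (concentration - c2)))
}

#' Generate a synthetic cyclic-voltammetry trace
#'
#' Builds the triangular potential program of the glucose-sensor CV
#' protocol (start +0.5 V, vertices +1.0 V and -1.2 V, 4 scans at 0.1 V/s)
#' and a current signal made of a linear baseline, a Gaussian-shaped anodic
#' oxidation peak at +0.72 V whose height follows
#' `gain * saturating_response(concentration)`, and i.i.d. Gaussian noise.
#' The saturating response is linear up to 6 mM, flat from 6 to 10 mM and
#' linear again from 10 mM, so calibration code can be exercised against
#' the published linear-range structure. This is a statistical emulation of
#' a voltammogram, not an electrochemical simulation.
#'
#' @param concentration analyte concentration in mol/L (>= 0).
#' @param gain peak-height gain in A per (mol/L) of effective response.
#' @param peak_potential,peak_width Gaussian peak centre and standard
#'   deviation, V.
#' @param baseline intercept and slope `c(a, b)` of the linear baseline
#'   current `a + b * E`, A and A/V.
#' @param noise_sd current noise standard deviation, A.
#' @param start,high,low potential program vertices, V.
#' @param scans number of full cycles after the initial rise.
#' @param scan_rate sweep rate, V/s.
#' @param dE potential step between samples, V.
#' @param breaks linear-range breakpoints of the saturating response, mol/L.
#' @param seed RNG seed.
#' @return A `cv_trace`: data.frame with `time` (s), `potential` (V),
#'   `current` (A); generator parameters stored as attributes.
#' @examples
#' tr <- gen_cv_trace(2e-3, seed = 1)
#' extract_peak_current(tr)
#' @export
gen_cv_trace <- function(concentration, gain = 2e-3,
                         peak_potential = 0.72, peak_width = 0.05,
                         baseline = c(1e-6, 2e-6), noise_sd = 1e-8,
                         start = 0.5, high = 1.0, low = -1.2,
                         scans = 4, scan_rate = 0.1, dE = 0.002,
                         breaks = c(6e-3, 10e-3), seed = NULL) {
  check_number(concentration, "concentration", lower = 0)
  check_number(scan_rate, "scan_rate", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!(low < start && start < high))
    stopf("need low < start < high potentials")
  up1 <- seq(start, high, by = dE)
  down <- seq(high, low, by = -dE)
  up <- seq(low, high, by = dE)
  E <- c(up1, rep(c(down[-1], up[-1]), scans))   # ends on a full anodic sweep
  tt <- (seq_along(E) - 1) * dE / scan_rate
  anodic <- c(TRUE, diff(E) > 0)
  height <- gain * saturating_response(concentration, breaks)
  peak <- ifelse(anodic, height * exp(-(E - peak_potential)^2 / (2 * peak_width^2)), 0)
  current <- with_seed(seed,
    baseline[1] + baseline[2] * E + peak + rnorm(length(E), 0, noise_sd))
  structure(data.frame(time = tt, potential = E, current = current),
            kind = "CV", concentration = concentration, gain = gain,
            peak_potential = peak_potential, peak_width = peak_width,
            baseline = baseline, noise_sd = noise_sd,
            start = start, high = high, low = low, scans = scans,
            scan_rate = scan_rate, dE = dE, breaks = breaks, seed = seed,
            class = c("cv_trace", "data.frame"))
}

#' Generate replicate blank traces
#'
#' Convenience wrapper producing `n` zero-concentration CV traces with
#' consecutive seeds, for blank-noise estimation in the limit-of-detection
#' workflow.
#'
#' @param n number of blank traces.
#' @param seed base seed; trace i uses `seed + i - 1`.
#' @param ... passed to [gen_cv_trace()].
#' @return List of `cv_trace` objects.
#' @examples
#' length(gen_blank_traces(10, seed = 1))
#' @export
gen_blank_traces <- function(n = 10, seed = 1, ...) {
  lapply(seq_len(n), function(i) gen_cv_trace(0, seed = seed + i - 1, ...))
}

#' Generate a synthetic calibration series from CV traces
#'
#' Runs the full synthetic chain: one CV trace per concentration, peak
#' extraction, and assembly into a calibration table.
#'
#' @param concentrations concentrations in mol/L.
#' @param seed base seed; trace i uses `seed + i - 1`.
#' @param window peak-extraction window in V.
#' @param ... passed to [gen_cv_trace()].
#' @return data.frame with `concentration` (mol/L) and `response` (A).
#' @examples
#' pts <- gen_cv_calibration((0:6) * 1e-3, seed = 2)
#' build_calibration(pts)
#' @export
gen_cv_calibration <- function(concentrations, seed = 1, window = 0.3, ...) {
  resp <- vapply(seq_along(concentrations), function(i) {
    tr <- gen_cv_trace(concentrations[i], seed = seed + i - 1, ...)
    as.numeric(suppressWarnings(extract_peak_current(tr, window = window)))
  }, 0)
  data.frame(concentration = concentrations, response = resp)
}

#' Randomly perturb tissue thermophysical parameters
#'
#' Multiplies each strictly positive thermophysical parameter (density,
#' conductivity, specific heat, metabolic heat, perfusion) of each material
#' by an independent factor uniform in `[1 - fraction, 1 + fraction]`.
#' Zero-valued parameters stay exactly zero (an unperfused epidermis stays
#' unperfused), and the arterial blood temperature is held fixed - it is a
#' physiological boundary value, not a tissue property to jitter. Used for
#' robustness sweeps of the solver.
#'
#' @param materials named list of [material_props()] (e.g.
#'   [tissue_materials()]).
#' @param fraction perturbation half-width in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return Named list of perturbed [material_props()].
#' @examples
#' p <- perturb_tissue_params(tissue_materials(), 0.1, seed = 3)
#' p$epidermis$perfusion == 0
#' @export
perturb_tissue_params <- function(materials, fraction, seed = NULL) {
  check_number(fraction, "fraction", lower = 0, upper = 0.5)
  stopifnot(all(vapply(materials, inherits, TRUE, "material_props")))
  with_seed(seed, lapply(materials, function(m) {
    for (f in c("density", "conductivity", "specific_heat",
                "metabolic_heat", "perfusion")) {
      if (m[[f]] > 0) m[[f]] <- m[[f]] * runif(1, 1 - fraction, 1 + fraction)
    }
    m
  }))
}
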
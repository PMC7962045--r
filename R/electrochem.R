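#' Extract the baseline-corrected anodic peak current from a CV trace
#'
#' On the final anodic (increasing-potential) sweep of a cyclic voltammetry
#' trace, fits a linear baseline through the trace values at the two edges
#' of a potential window centred on the expected oxidation peak and returns
#' the maximum baseline-corrected current inside the window. Correction by
#' an interpolated straight line makes the result exactly invariant to any
#' global linear baseline added to the trace. Reading the final scan
#' discards the conditioning sweeps.
#'
#' @param trace a `cv_trace` (see [gen_cv_trace()] or [read_trace()]): a
#'   data.frame with columns `potential` (V) and `current` (A).
#' @param peak_potential expected peak position in V (default +0.72, the
#'   glucose-mediated ferrocenemethanol oxidation peak).
#' @param window full window width in V; must sit inside the anodic sweep
#'   and should span at least ~6 peak widths for accurate height recovery.
#' @param at if supplied, return the baseline-corrected current at this
#'   fixed potential instead of the window maximum. This is how blank
#'   replicates are read (at the analyte's nominal signal position): the
#'   maximum of pure noise over a window is an extreme-value statistic whose
#'   dispersion does not estimate the per-point blank noise.
#' @param edge_frac fraction of window samples averaged on each edge to
#'   anchor the baseline (default 0.05); the line through the two edge
#'   means stays exactly linear-baseline-invariant while damping noise.
#' @return Peak current in A (baseline-corrected). Attribute `"edge"` is
#'   `TRUE` (with a warning) when the maximum sits on the window edge (no
#'   interior local maximum); attribute `"at"` is the potential of the
#'   returned value.
#' @examples
#' tr <- gen_cv_trace(4e-3, seed = 1)
#' extract_peak_current(tr)
#' @export
extract_peak_current <- function(trace, peak_potential = 0.72, window = 0.3,
                                 at = NULL, edge_frac = 0.05) {
  if (!is.data.frame(trace) || !all(c("potential", "current") %in% names(trace)))
    stopf("`trace` must have columns `potential` and `current`")
  check_number(peak_potential, "peak_potential")
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  check_number(edge_frac, "edge_frac", lower = 0, upper = 0.45, strict_lower = TRUE)
  lo <- peak_potential - window / 2; hi <- peak_potential + window / 2

  E <- trace$potential; I <- trace$current
  dE <- diff(E)
  # contiguous runs of increasing potential = anodic sweeps
  runs <- rle(dE > 0)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  anodic <- which(runs$values)
  if (!length(anodic)) stopf("trace has no anodic sweep")
  seg <- NULL
  for (a in rev(anodic)) {
    s <- starts[a]; e <- ends[a] + 1L   # run over diffs -> +1 sample
    if (E[s] <= lo && E[e] >= hi) { seg <- s:e; break }
  }
  if (is.null(seg))
    stopf("window [%.3g, %.3g] V not contained in any anodic sweep", lo, hi)

  Es <- E[seg]; Is <- I[seg]
  iw <- which(Es >= lo & Es <= hi)
  m <- max(1L, floor(edge_frac * length(iw)))
  g1 <- iw[seq_len(m)]; g2 <- iw[seq.int(length(iw) - m + 1L, length(iw))]
  E1 <- mean(Es[g1]); I1 <- mean(Is[g1])
  E2 <- mean(Es[g2]); I2 <- mean(Is[g2])
  base <- I1 + (I2 - I1) * (Es - E1) / (E2 - E1)
  corr <- Is - base
  if (!is.null(at)) {
    check_number(at, "at", lower = lo, upper = hi)
    ia <- iw[which.min(abs(Es[iw] - at))]
    return(structure(corr[ia], at = Es[ia], edge = FALSE))
  }
  im <- iw[which.max(corr[iw])]
  edge <- im == iw[1L] || im == iw[length(iw)]
  if (edge) warning("maximum sits on the window edge (no interior local maximum)")
  structure(corr[im], at = Es[im], edge = edge)
}

#' Fit a linear calibration of sensor response on concentration
#'
#' Ordinary least squares of response (normalised peak current, or raw
#' current in A) on analyte concentration, restricted to a stated fit
#' range. The slope is the sensitivity of the sensor over that range;
#' divide by the electrode area with [sensitivity_per_area()].
#'
#' @param points data.frame with columns `concentration` (mol/L) and
#'   `response`.
#' @param fit_range concentration interval (mol/L) to fit over; `NULL` uses
#'   all points. At least 3 in-range points are required.
#' @return A `calibration_fit`: `slope`, `intercept`, `slope_stderr`,
#'   `r_squared`, `n`, `fit_range`, and the underlying `lm`.
#' @examples
#' pts <- data.frame(concentration = (0:6) * 1e-3, response = (0:6) * 2)
#' build_calibration(pts, fit_range = c(0, 6e-3))
#' @export
build_calibration <- function(points, fit_range = NULL) {
  if (!is.data.frame(points) ||
      !all(c("concentration", "response") %in% names(points)))
    stopf("`points` must have columns `concentration` and `response`")
  if (any(points$concentration < 0)) stopf("concentrations must be >= 0")
  sel <- if (is.null(fit_range)) rep(TRUE, nrow(points))
         else points$concentration >= fit_range[1] - 1e-15 &
              points$concentration <= fit_range[2] + 1e-15
  d <- points[sel, ]
  if (nrow(d) < 3L) stopf("fewer than 3 calibration points in the fit range")
  fit <- stats::lm(response ~ concentration, data = d)
  sm <- quiet_perfect_fit(summary(fit))
  r2 <- if (all(d$response == d$response[1])) 0 else sm$r.squared
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 slope_stderr = sm$coefficients[2, 2],
                 r_squared = r2, n = nrow(d),
                 fit_range = fit_range, fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope = %.4g +- %.2g per mol/L (n = %d, r2 = %.4f)\n",
              x$slope, x$slope_stderr, x$n, x$r_squared))
  if (!is.null(x$fit_range))
    cat(sprintf("  fit range: %.3g-%.3g mol/L (%.3g-%.3g mM)\n",
                x$fit_range[1], x$fit_range[2],
                1e3 * x$fit_range[1], 1e3 * x$fit_range[2]))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.calibration_fit <- function(object, concentration, ...)
  object$intercept + object$slope * concentration

# r-squared of an OLS line through (x, y); 0 when y carries no variance
window_r2 <- function(x, y) {
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  if (syy <= 0 || sxx <= 0) return(0)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy^2) / (sxx * syy)
}

#' Identify linear sensing ranges of a calibration series
#'
#' Finds maximal contiguous concentration windows (at least `min_points`
#' points) whose ordinary-least-squares \eqn{r^2} stays at or above
#' `r2_min`. Windows are grown greedily from the low-concentration end;
#' after a window closes (or a start fails), the search restarts from the
#' next point, so a response that is linear up to a plateau and linear again
#' beyond it yields two windows. The procedure is deterministic.
#'
#' @param points data.frame with `concentration` (mol/L, sorted increasing)
#'   and `response`.
#' @param r2_min minimum \eqn{r^2} in (0, 1).
#' @param min_points minimum number of points per window (>= 3).
#' @return data.frame with one row per window: `from`, `to` (mol/L), `n`,
#'   `r_squared`, `slope`. Zero rows when no window qualifies.
#' @examples
#' pts <- data.frame(concentration = (0:10) * 1e-3,
#'                   response = pmin(0:10, 6) * 2)
#' detect_linear_range(pts, r2_min = 0.99)
#' @export
detect_linear_range <- function(points, r2_min = 0.99, min_points = 4L) {
  if (!is.data.frame(points) ||
      !all(c("concentration", "response") %in% names(points)))
    stopf("`points` must have columns `concentration` and `response`")
  check_number(r2_min, "r2_min", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  min_points <- as.integer(min_points)
  if (min_points < 3L) stopf("`min_points` must be >= 3")
  x <- points$concentration; y <- points$response
  if (is.unsorted(x)) stopf("`points` must be sorted by concentration")
  n <- length(x)
  out <- list(); start <- 1L
  while (start + min_points - 1L <= n) {
    end <- start + min_points - 1L
    if (window_r2(x[start:end], y[start:end]) >= r2_min) {
      while (end < n && window_r2(x[start:(end + 1L)], y[start:(end + 1L)]) >= r2_min)
        end <- end + 1L
      fit <- stats::lm(y[start:end] ~ x[start:end])
      out[[length(out) + 1L]] <- data.frame(
        from = x[start], to = x[end], n = end - start + 1L,
        r_squared = window_r2(x[start:end], y[start:end]),
        slope = unname(coef(fit)[2]))
      start <- end + 1L
    } else start <- start + 1L
  }
  if (!length(out))
    return(data.frame(from = numeric(0), to = numeric(0), n = integer(0),
                      r_squared = numeric(0), slope = numeric(0)))
  do.call(rbind, out)
}

#' Limit of detection from blank noise and calibration slope
#'
#' \eqn{LOD = k \,\sigma_{blank} / S}: the smallest concentration whose
#' response stands out from the blank, following the IUPAC blank-based
#' definition with the conventional multiplier \eqn{k = 3.3}. The blank
#' standard deviation should come from repeated blank-trace peak
#' extractions (see [estimate_blank_sd()]), not from fit residuals. The
#' result is invariant to rescaling of the response units, since sigma and
#' the slope co-scale.
#'
#' @param blank_sd standard deviation of the blank response (response units).
#' @param slope calibration slope (response units per mol/L, > 0).
#' @param k multiplier (default 3.3).
#' @return LOD in mol/L.
#' @examples
#' limit_of_detection(blank_sd = 1e-8, slope = 2e-3)  # mol/L
#' @export
limit_of_detection <- function(blank_sd, slope, k = 3.3) {
  check_number(blank_sd, "blank_sd", lower = 0)
  check_number(slope, "slope", lower = 0, strict_lower = TRUE)
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  k * blank_sd / slope
}

#' Standard deviation of blank-trace peak responses
#'
#' @param traces list of blank `cv_trace` objects (concentration zero), at
#'   least 10 recommended.
#' @param peak_potential potential at which blank responses are read, V.
#' @param ... passed to [extract_peak_current()].
#' @return Standard deviation of the blank responses (A), each read at the
#'   nominal peak potential after baseline correction.
#' @examples
#' blanks <- gen_blank_traces(10, seed = 7)
#' estimate_blank_sd(blanks)
#' @export
estimate_blank_sd <- function(traces, peak_potential = 0.72, ...) {
  if (!is.list(traces) || length(traces) < 2L)
    stopf("`traces` must be a list of at least 2 blank traces")
  peaks <- vapply(traces, function(tr)
    as.numeric(extract_peak_current(tr, peak_potential = peak_potential,
                                    at = peak_potential, ...)), 0)
  stats::sd(peaks)
}

#' Area-normalised sensitivity
#'
#' @param slope calibration slope (current per mol/L).
#' @param electrode_area electrode area in cm2 (> 0).
#' @return Sensitivity per unit area (same current units per mol/L per cm2).
#' @examples
#' sensitivity_per_area(21, 1)
#' @export
sensitivity_per_area <- function(slope, electrode_area) {
  check_number(electrode_area, "electrode_area", lower = 0, strict_lower = TRUE)
  slope / electrode_area
}

#' Glucose concentration unit conversions
#'
#' 1 mmol/L of glucose is 18.016 mg/dL (molar mass 180.16 g/mol), so the
#' 0-6 mM application range corresponds to 0-108 mg/dL.
#'
#' @param x concentration(s) to convert.
#' @return Converted concentration(s).
#' @examples
#' glucose_mM_to_mgdl(6)      # 108.1
#' glucose_mgdl_to_mM(glucose_mM_to_mgdl(2.5))
#' @export
glucose_mM_to_mgdl <- function(x) x * MGDL_PER_MM

#' @rdname glucose_mM_to_mgdl
#' @export
glucose_mgdl_to_mM <- function(x) x / MGDL_PER_MM
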
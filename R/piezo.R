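#' Fit the charge-force line of a piezoelectric pressure sensor
#'
#' Ordinary least squares of generated charge (pC) on applied normal force
#' (N). The slope is the longitudinal piezoelectric coefficient d33 in pC/N;
#' the intercept is estimated rather than forced through zero so that
#' baseline offsets in the acquisition chain show up in QA rather than bias
#' the slope.
#'
#' @param force applied forces in N, or a data.frame with columns
#'   `force` and `charge` (e.g. from [gen_charge_force()] or
#'   [read_xy_table()]).
#' @param charge generated charges in pC (when `force` is a vector).
#' @param force_range declared admissible force range in N; points outside
#'   raise an error (default 0-4 N, the quasi-static test range).
#' @return A `charge_force_fit`: `d33` (pC/N), `intercept` (pC),
#'   `d33_stderr`, `r_squared`, `n`, and the underlying `lm` fit.
#' @examples
#' fit <- fit_charge_force(c(0, 4), c(0, 18))
#' coef(fit)          # slope 4.5 pC/N
#' @export
fit_charge_force <- function(force, charge = NULL, force_range = c(0, 4)) {
  if (is.data.frame(force)) {
    if (!all(c("force", "charge") %in% names(force)))
      stopf("data.frame input needs columns `force` and `charge`")
    charge <- force$charge; force <- force$force
  }
  if (length(force) != length(charge) || length(force) < 2L)
    stopf("need at least 2 paired (force, charge) samples")
  if (any(!is.finite(force)) || any(!is.finite(charge)))
    stopf("non-finite values in the series")
  if (any(force < force_range[1] - 1e-9 | force > force_range[2] + 1e-9))
    stopf("forces outside the declared range [%g, %g] N",
          force_range[1], force_range[2])
  if (length(unique(force)) < 2L)
    stopf("all forces identical: the slope is not identifiable")
  fit <- stats::lm(charge ~ force)
  sm <- quiet_perfect_fit(summary(fit))
  structure(list(d33 = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 d33_stderr = sm$coefficients[2, 2],
                 r_squared = sm$r.squared, n = length(force), fit = fit),
            class = "charge_force_fit")
}

#' @export
print.charge_force_fit <- function(x, ...) {
  cat(sprintf("<charge_force_fit> d33 = %.3f +- %.3f pC/N (n = %d, r2 = %.4f)\n",
              x$d33, x$d33_stderr, x$n, x$r_squared))
  cat(sprintf("  intercept %.3f pC\n", x$intercept))
  invisible(x)
}

#' @export
coef.charge_force_fit <- function(object, ...)
  c(intercept = object$intercept, d33 = object$d33)

#' Predict generated charge at given forces
#'
#' @param object a [fit_charge_force()] result.
#' @param force forces in N.
#' @param ... unused.
#' @return Predicted charge in pC.
#' @export
predict.charge_force_fit <- function(object, force, ...)
  object$intercept + object$d33 * force

#' Piezoelectric figure of merit
#'
#' \eqn{d_{31}^2 / (\epsilon_0 \epsilon_r)}, the energy-conversion metric
#' combining the transverse piezoelectric constant (C/m2) with the film's
#' relative permittivity; units of pressure (Pa). Quadratic in `d31`, so the
#' sign of the coefficient does not matter.
#'
#' @param d31 transverse piezoelectric constant in C/m2.
#' @param eps_r relative permittivity (> 0).
#' @return Figure of merit in Pa.
#' @examples
#' figure_of_merit(0.7, 10.55) / 1e9   # about 5.25 GPa
#' @export
figure_of_merit <- function(d31, eps_r) {
  check_number(d31, "d31")
  check_number(eps_r, "eps_r", lower = 0, strict_lower = TRUE)
  d31^2 / (EPSILON0 * eps_r)
}

#' Convert a normal force on a circular contact to pressure
#'
#' @param force force in N (vectorised).
#' @param contact_diameter contact (electrode) diameter in m (> 0).
#' @return Pressure in Pa.
#' @examples
#' force_to_pressure(4, 3.8e-3) / 1e3  # about 353 kPa
#' @export
force_to_pressure <- function(force, contact_diameter) {
  check_number(contact_diameter, "contact_diameter", lower = 0, strict_lower = TRUE)
  force / (pi * (contact_diameter / 2)^2)
}
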
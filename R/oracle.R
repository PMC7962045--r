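# Per-layer basis for the 1-D steady Pennes solution, in a local coordinate
# zeta in [0, L] measured downward from the layer's top face.
#
# Perfused layer (omega_b > 0), m = sqrt(rho_b Cp_b omega_b / k):
#   T(zeta) = Teq + A exp(-m zeta) + B exp(-m (L - zeta))
# The scaled exponential pair keeps both basis functions <= 1 on the layer,
# so large m L cannot overflow.
# Unperfused layer: T(zeta) = -Qmet zeta^2 / (2 k) + A zeta + B.
oracle_basis <- function(lay, blood) {
  m <- lay$material
  if (m$perfusion > 0) {
    P <- blood$density * blood$specific_heat * m$perfusion
    mm <- sqrt(P / m$conductivity)
    Teq <- m$blood_temperature + m$metabolic_heat / P
    list(
      perfused = TRUE, m = mm, Teq = Teq, L = lay$thickness, k = m$conductivity,
      value = function(z) c(exp(-mm * z), exp(-mm * (lay$thickness - z)), Teq),
      deriv = function(z) c(-mm * exp(-mm * z), mm * exp(-mm * (lay$thickness - z)), 0))
  } else {
    k <- m$conductivity; Q <- m$metabolic_heat
    list(
      perfused = FALSE, L = lay$thickness, k = k,
      value = function(z) c(z, 1, -Q * z^2 / (2 * k)),
      deriv = function(z) c(1, 0, -Q * z / k))
  }
}

#' Closed-form 1-D multilayer steady Pennes solution
#'
#' Solves the steady one-dimensional Pennes equation through an ordered
#' layer stack analytically: perfused layers take the form
#' \eqn{T_{eq} + A e^{m z} + B e^{-m z}} with
#' \eqn{m = \sqrt{\rho_b C_{p,b} \omega_b / k}} and
#' \eqn{T_{eq} = T_b + Q_{met}/(\rho_b C_{p,b}\omega_b)}; unperfused layers
#' are quadratic. Coefficients come from the banded linear system of
#' interface temperature/flux continuity (with the sock contact-resistance
#' jump where configured) and the boundary conditions. This is the
#' verification oracle for the 3-D finite-volume solver.
#'
#' @param layers list of [layer()] objects, top first.
#' @param blood a [blood_props()].
#' @param bc a [boundary_spec()]; the lateral condition is irrelevant in 1-D.
#' @return An object of class `pennes_profile`: evaluate with
#'   `predict(sol, z)` at depths `z` (m, measured from the top face).
#' @examples
#' sol <- solve_1d(foot_insole_layers(), blood_props(), boundary_spec())
#' predict(sol, c(0, 0.0338))
#' @export
solve_1d <- function(layers, blood = blood_props(), bc = boundary_spec()) {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec")))
    stopf("`layers` must be a non-empty list of layer_spec objects")
  if (!inherits(blood, "blood_props")) stopf("`blood` must be a blood_props")
  if (!inherits(bc, "boundary_spec")) stopf("`bc` must be a boundary_spec")
  n <- length(layers)
  perfused_any <- any(vapply(layers, function(l) l$material$perfusion > 0, TRUE))
  if (bc$floor_h == 0 && bc$top == "adiabatic" && !perfused_any)
    stopf("degenerate configuration: no boundary anchor and no perfusion")

  basis <- lapply(layers, oracle_basis, blood = blood)
  # sock interface: after the last tissue layer when insole layers follow
  tissue_flags <- vapply(layers, `[[`, TRUE, "tissue")
  sock_after <- if (any(tissue_flags) && any(!tissue_flags))
    max(which(tissue_flags)) else 0L

  M <- matrix(0, 2 * n, 2 * n); rhs <- numeric(2 * n); row <- 1L
  # heat flux q(zeta) = -k dT/dzeta; coefficient triplet (cA, cB, const)
  fluxc <- function(i, z) { d <- basis[[i]]$deriv(z); -basis[[i]]$k * d }
  valc <- function(i, z) basis[[i]]$value(z)

  # top boundary
  if (bc$top == "fixed") {
    v <- valc(1L, 0)
    M[row, 1:2] <- v[1:2]; rhs[row] <- bc$top_temperature - v[3]
  } else {
    f <- fluxc(1L, 0)
    M[row, 1:2] <- f[1:2]; rhs[row] <- -f[3]
  }
  row <- row + 1L
  # interfaces
  for (i in seq_len(n - 1L)) {
    Li <- basis[[i]]$L
    R <- if (i == sock_after) bc$sock_resistance else 0
    v1 <- valc(i, Li); f1 <- fluxc(i, Li)
    v2 <- valc(i + 1L, 0); f2 <- fluxc(i + 1L, 0)
    # temperature (with contact-resistance drop R * q across the interface)
    M[row, (2 * i - 1):(2 * i)] <- v1[1:2] - R * f1[1:2]
    M[row, (2 * i + 1):(2 * i + 2)] <- -v2[1:2]
    rhs[row] <- v2[3] - v1[3] + R * f1[3]
    row <- row + 1L
    # flux continuity
    M[row, (2 * i - 1):(2 * i)] <- f1[1:2]
    M[row, (2 * i + 1):(2 * i + 2)] <- -f2[1:2]
    rhs[row] <- f2[3] - f1[3]
    row <- row + 1L
  }
  # bottom boundary
  Ln <- basis[[n]]$L
  vn <- valc(n, Ln); fn <- fluxc(n, Ln)
  if (is.infinite(bc$floor_h)) {            # fixed floor temperature
    M[row, (2 * n - 1):(2 * n)] <- vn[1:2]
    rhs[row] <- bc$floor_T_env - vn[3]
  } else if (bc$floor_h > 0) {              # Robin: q = h (T - Tenv)
    M[row, (2 * n - 1):(2 * n)] <- fn[1:2] - bc$floor_h * vn[1:2]
    rhs[row] <- bc$floor_h * (vn[3] - bc$floor_T_env) - fn[3]
  } else {                                  # adiabatic floor
    M[row, (2 * n - 1):(2 * n)] <- fn[1:2]
    rhs[row] <- -fn[3]
  }

  co <- tryCatch(solve(M, rhs), error = function(e)
    stopf("singular interface system (degenerate configuration): %s", conditionMessage(e)))

  tops <- cumsum(c(0, vapply(layers, `[[`, 0, "thickness")))
  structure(list(layers = layers, blood = blood, bc = bc, basis = basis,
                 coefficients = co, tops = tops, sock_after = sock_after,
                 total = tops[n + 1L]),
            class = "pennes_profile")
}

#' Evaluate a 1-D Pennes profile at given depths
#'
#' @param object a [solve_1d()] solution.
#' @param z depths from the top face, m (vector). Points exactly on an
#'   interface evaluate on the upper layer's side.
#' @param derivative if `TRUE`, return the heat flux \eqn{-k\,dT/dz} (W/m2,
#'   positive downward) instead of the temperature.
#' @param ... unused.
#' @return Numeric vector, degC (or W/m2).
#' @export
predict.pennes_profile <- function(object, z, derivative = FALSE, ...) {
  if (any(z < -1e-12 | z > object$total + 1e-12))
    stopf("depth out of range [0, %g] m", object$total)
  n <- length(object$layers)
  vapply(pmin(pmax(z, 0), object$total), function(zz) {
    i <- findInterval(zz, object$tops, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n)
    zeta <- zz - object$tops[i]
    cf <- object$coefficients[(2 * i - 1):(2 * i)]
    if (derivative) {
      d <- object$basis[[i]]$deriv(zeta)
      -object$basis[[i]]$k * (sum(d[1:2] * cf) + d[3])
    } else {
      v <- object$basis[[i]]$value(zeta)
      sum(v[1:2] * cf) + v[3]
    }
  }, 0)
}

#' @export
print.pennes_profile <- function(x, ...) {
  cat(sprintf("<pennes_profile> %d layers, %.2f mm total\n",
              length(x$layers), 1e3 * x$total))
  cat(sprintf("  T(top) = %.4f degC, T(bottom) = %.4f degC, flux(bottom) = %.3f W/m2\n",
              predict(x, 0), predict(x, x$total),
              predict(x, x$total, derivative = TRUE)))
  invisible(x)
}

#' @export
plot.pennes_profile <- function(x, y, n = 400, ...) {
  z <- seq(0, x$total, length.out = n)
  graphics::plot(predict(x, z), z * 1e3, type = "l",
                 xlab = "T (degC)", ylab = "depth from top face (mm)",
                 ylim = rev(range(z * 1e3)), ...)
  abline(h = x$tops[-c(1, length(x$tops))] * 1e3, col = "grey80", lty = 3)
  invisible(x)
}

#' Compare a 3-D field against the 1-D oracle along a column
#'
#' For a laterally uniform configuration the 3-D finite-volume solution must
#' match the closed-form 1-D profile; this returns the maximum absolute
#' temperature deviation over the cell centres of one vertical column.
#'
#' @param field a [solve_steady()] result.
#' @param oracle a [solve_1d()] solution for the same stack and boundary
#'   conditions.
#' @param column lateral `(x, y)` position in m of the column to sample
#'   (default: domain centre).
#' @return Max absolute deviation in degC, with attribute `"profile"` (a
#'   data.frame of z, T_3d, T_1d).
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
#' f <- solve_steady(g)
#' compare_to_oracle(f, solve_1d(foot_insole_layers())) < 0.01
#' @export
compare_to_oracle <- function(field, oracle, column = NULL) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(oracle, "pennes_profile"))
  g <- field$grid
  if (abs(max(g$z_edges) - oracle$total) > 1e-12)
    stopf("layer stacks differ: 3-D depth %.6g m vs 1-D depth %.6g m",
          max(g$z_edges), oracle$total)
  thick3 <- vapply(g$layers, `[[`, 0, "thickness")
  thick1 <- vapply(oracle$layers, `[[`, 0, "thickness")
  if (length(thick3) != length(thick1) || any(abs(thick3 - thick1) > 1e-12))
    stopf("layer stacks differ between field and oracle")
  if (is.null(column))
    column <- c(max(g$x_edges) / 2, max(g$y_edges) / 2)
  i <- which.min(abs(cell_centers(g$x_edges) - column[1]))
  j <- which.min(abs(cell_centers(g$y_edges) - column[2]))
  zc <- cell_centers(g$z_edges)
  t3 <- field$T[i, j, ]
  t1 <- predict(oracle, zc)
  structure(max(abs(t3 - t1)),
            profile = data.frame(z = zc, T_3d = t3, T_1d = t1))
}
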
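#' Boundary conditions for the steady bioheat solve
#'
#' The floor face (below the shoe sole) exchanges heat by convection
#' (Robin condition \eqn{q = h (T - T_{env})}); lateral faces are adiabatic;
#' the top (deep/proximal) face is adiabatic by default - the perfusion sink
#' anchors deep tissue near the arterial temperature without imposing it -
#' or can be fixed at a temperature. A worn sock is modelled as an
#' area-specific contact resistance in series on the faces crossing the
#' skin-insole interface.
#'
#' @param floor_h floor heat transfer coefficient, W/m2/K (>= 0; `Inf` for a
#'   fixed floor temperature).
#' @param floor_T_env environment temperature below the floor, degC.
#' @param top `"adiabatic"` or `"fixed"`.
#' @param top_temperature temperature of the top face when `top = "fixed"`, degC.
#' @param sock_resistance sock contact resistance, m2K/W (0 disables). The
#'   published sock value 0.02 is stated in conductivity units (W/m/K); it is
#'   interpreted here as the area-specific resistance 0.02 m2K/W, the
#'   magnitude of a thin worn sock.
#' @return An object of class `boundary_spec`.
#' @examples
#' boundary_spec()                       # floor convection h = 5 at 20 degC, sock on
#' boundary_spec(sock_resistance = 0)    # barefoot on the insole
#' @export
boundary_spec <- function(floor_h = 5, floor_T_env = 20,
                          top = c("adiabatic", "fixed"), top_temperature = NULL,
                          sock_resistance = 0.02) {
  top <- match.arg(top)
  if (!identical(floor_h, Inf)) check_number(floor_h, "floor_h", lower = 0)
  check_number(floor_T_env, "floor_T_env")
  check_number(sock_resistance, "sock_resistance", lower = 0)
  if (top == "fixed") {
    if (is.null(top_temperature)) stopf("`top_temperature` required when top = \"fixed\"")
    check_number(top_temperature, "top_temperature")
  } else top_temperature <- NULL
  structure(list(floor_h = floor_h, floor_T_env = floor_T_env,
                 top = top, top_temperature = top_temperature,
                 sock_resistance = sock_resistance, lateral = "adiabatic"),
            class = "boundary_spec")
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat(sprintf("<boundary_spec> floor: h = %g W/m2/K at %g degC; top: %s%s; sock R = %g m2K/W\n",
              x$floor_h, x$floor_T_env, x$top,
              if (x$top == "fixed") sprintf(" (%g degC)", x$top_temperature) else "",
              x$sock_resistance))
  invisible(x)
}

# per-cell property arrays from the material table
cell_props <- function(grid, blood) {
  mats <- grid$materials
  kv  <- vapply(mats, `[[`, 0, "conductivity")
  qv  <- vapply(mats, `[[`, 0, "metabolic_heat")
  wv  <- vapply(mats, `[[`, 0, "perfusion")
  tbv <- vapply(mats, `[[`, 0, "blood_temperature")
  id <- grid$mat
  list(K = array(kv[id], dim(id)),
       Q = array(qv[id], dim(id)),
       P = array(blood$density * blood$specific_heat * wv[id], dim(id)),
       Tb = array(tbv[id], dim(id)))
}

# Assemble the SPD finite-volume system A T = b.
# Face conductances use half-cell series resistances (harmonic mean of the
# two cell conductivities for equal spacing); faces crossing the sock
# interface get the contact resistance added in series.
assemble_system <- function(grid, blood, bc) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- nx * ny * nz
  dxv <- diff(grid$x_edges); dyv <- diff(grid$y_edges); dzv <- diff(grid$z_edges)
  pr <- cell_props(grid, blood)
  K <- pr$K

  idx <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  DX <- array(dxv, c(nx, ny, nz))
  DY <- array(rep(dyv, each = nx), c(nx, ny, nz))
  DZ <- array(rep(dzv, each = nx * ny), c(nx, ny, nz))
  V <- DX * DY * DZ
  # half-cell thermal resistances per unit area
  RX <- DX / (2 * K); RY <- DY / (2 * K); RZ <- DZ / (2 * K)

  fp <- fq <- integer(0); fg <- numeric(0)
  if (nx > 1L) {
    i <- rep(seq_len(nx - 1L), times = ny * nz)
    j <- rep(rep(seq_len(ny), each = nx - 1L), times = nz)
    k <- rep(seq_len(nz), each = (nx - 1L) * ny)
    p <- idx(i, j, k); q <- idx(i + 1L, j, k)
    g <- (DY[p] * DZ[p]) / (RX[p] + RX[q])
    fp <- c(fp, p); fq <- c(fq, q); fg <- c(fg, g)
  }
  if (ny > 1L) {
    i <- rep(seq_len(nx), times = (ny - 1L) * nz)
    j <- rep(rep(seq_len(ny - 1L), each = nx), times = nz)
    k <- rep(seq_len(nz), each = nx * (ny - 1L))
    p <- idx(i, j, k); q <- idx(i, j + 1L, k)
    g <- (DX[p] * DZ[p]) / (RY[p] + RY[q])
    fp <- c(fp, p); fq <- c(fq, q); fg <- c(fg, g)
  }
  if (nz > 1L) {
    i <- rep(seq_len(nx), times = ny * (nz - 1L))
    j <- rep(rep(seq_len(ny), each = nx), times = nz - 1L)
    k <- rep(seq_len(nz - 1L), each = nx * ny)
    p <- idx(i, j, k); q <- idx(i, j, k + 1L)
    rextra <- ifelse(!is.na(grid$sock_face) & k == grid$sock_face,
                     bc$sock_resistance, 0)
    g <- (DX[p] * DY[p]) / (RZ[p] + RZ[q] + rextra)
    fp <- c(fp, p); fq <- c(fq, q); fg <- c(fg, g)
  }

  diagv <- numeric(n)
  acc <- rowsum(c(fg, fg), c(fp, fq))
  diagv[as.integer(rownames(acc))] <- acc
  rhs <- as.vector(V * (pr$Q + pr$P * pr$Tb))
  diagv <- diagv + as.vector(V * pr$P)

  # floor (bottom, k = nz): Robin through the half cell + film resistance
  Gb <- NULL
  if (bc$floor_h > 0) {
    i <- rep(seq_len(nx), times = ny); j <- rep(seq_len(ny), each = nx)
    p <- idx(i, j, rep(nz, nx * ny))
    film <- if (is.infinite(bc$floor_h)) 0 else 1 / bc$floor_h
    Gb <- (DX[p] * DY[p]) / (RZ[p] + film)
    diagv[p] <- diagv[p] + Gb
    rhs[p] <- rhs[p] + Gb * bc$floor_T_env
  }
  # top (k = 1): fixed temperature via half-cell conductance
  Gt <- NULL
  if (bc$top == "fixed") {
    i <- rep(seq_len(nx), times = ny); j <- rep(seq_len(ny), each = nx)
    p <- idx(i, j, rep(1L, nx * ny))
    Gt <- (DX[p] * DY[p]) / RZ[p]
    diagv[p] <- diagv[p] + Gt
    rhs[p] <- rhs[p] + Gt * bc$top_temperature
  }

  if (is.null(Gb) && is.null(Gt) && all(pr$P == 0))
    stopf(paste("singular system: all boundaries adiabatic and no perfusion anywhere -",
                "the temperature level has no anchor"))

  A <- Matrix::sparseMatrix(i = fp, j = fq, x = -fg, dims = c(n, n),
                            symmetric = TRUE) + Matrix::Diagonal(n, diagv)
  list(A = Matrix::forceSymmetric(A), b = rhs, V = V, props = pr,
       Gb = Gb, Gt = Gt, n = n)
}

#' Solve the steady-state Pennes bioheat equation
#'
#' Finite-volume discretization of
#' \eqn{\nabla\cdot(k \nabla T) + \rho_b C_{p,b}\omega_b (T_b - T) + Q_{met} = 0}
#' on a [build_domain()] grid, with convective floor, adiabatic lateral
#' faces, optional fixed top temperature and an optional sock contact
#' resistance at the skin-insole interface. The symmetric positive-definite
#' system is solved by sparse Cholesky factorization (default) or by Jacobi
#' preconditioned conjugate gradients.
#'
#' @param grid a `domain_grid`.
#' @param blood a [blood_props()] object.
#' @param bc a [boundary_spec()].
#' @param tol maximum admissible relative residual, in (0, 1e-4].
#' @param method `"direct"` (sparse Cholesky) or `"cg"`.
#' @param maxit iteration cap for `method = "cg"`.
#' @param factor a Cholesky factor from a previous solve on the same grid
#'   pattern (see `keep_factor`); reused symbolically for fast re-solves.
#' @param keep_factor if `TRUE`, attach the Cholesky factor to the result as
#'   attribute `"factor"` so sweeps can reuse the symbolic analysis.
#' @return An object of class `temperature_field`: `T` (degC per cell,
#'   `nx x ny x nz`), `residual` (relative), `boundary_flux` (W out of the
#'   floor/top face groups), `source_total` (W), plus the `grid`, `blood`
#'   and `bc` used.
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
#' f <- solve_steady(g)
#' summary(f)
#' @export
solve_steady <- function(grid, blood = blood_props(), bc = boundary_spec(),
                         tol = 1e-10, method = c("direct", "cg"),
                         maxit = 20000L, factor = NULL, keep_factor = FALSE) {
  if (!inherits(grid, "domain_grid")) stopf("`grid` must be a domain_grid")
  if (!inherits(blood, "blood_props")) stopf("`blood` must be a blood_props")
  if (!inherits(bc, "boundary_spec")) stopf("`bc` must be a boundary_spec")
  check_number(tol, "tol", lower = 0, upper = 1e-4, strict_lower = TRUE)
  method <- match.arg(method)

  sys <- assemble_system(grid, blood, bc)
  ch <- NULL
  if (method == "direct") {
    ch <- if (is.null(factor)) Matrix::Cholesky(sys$A, LDL = FALSE, super = TRUE)
          else Matrix::update(factor, sys$A)
    x <- as.numeric(Matrix::solve(ch, sys$b))
    # iterative refinement: strong material contrasts (copper vs polyurethane)
    # leave a normwise residual above round-off after one backsolve
    r <- sys$b - as.numeric(sys$A %*% x)
    x <- x + as.numeric(Matrix::solve(ch, r))  # one refinement step
  } else {
    x <- pcg_solve(sys$A, sys$b, tol = tol, maxit = maxit)
  }
  # normwise backward error ||Ax - b|| / (||A|| ||x|| + ||b||): the achievable
  # floor under strong material contrasts, unlike ||r|| / ||b||
  nrmA <- sqrt(sum(sys$A@x^2))
  resid <- sqrt(sum(as.numeric(sys$A %*% x - sys$b)^2)) /
    max(nrmA * sqrt(sum(x^2)) + sqrt(sum(sys$b^2)), .Machine$double.xmin)
  if (resid > tol)
    stopf("solver did not reach tol = %g (relative residual %.3g)", tol, resid)

  Tarr <- array(x, dim = c(grid$nx, grid$ny, grid$nz))
  flux <- list(floor = 0, top = 0)
  if (!is.null(sys$Gb))
    flux$floor <- sum(sys$Gb * (Tarr[, , grid$nz] - bc$floor_T_env))
  if (!is.null(sys$Gt))
    flux$top <- sum(sys$Gt * (Tarr[, , 1] - bc$top_temperature))
  src <- sum(sys$V * (sys$props$Q + sys$props$P * (sys$props$Tb - Tarr)))

  out <- structure(list(T = Tarr, grid = grid, blood = blood, bc = bc,
                        residual = resid, boundary_flux = flux,
                        source_total = src, method = method),
                   class = "temperature_field")
  if (keep_factor && !is.null(ch)) attr(out, "factor") <- ch
  out
}

# Jacobi-preconditioned conjugate gradients (kept for residual/energy studies:
# a loose `tol` yields a visibly imperfect energy balance).
pcg_solve <- function(A, b, tol, maxit) {
  d <- Matrix::diag(A)
  x <- rep(mean(b / d), length(b))
  r <- b - as.numeric(A %*% x)
  nb <- sqrt(sum(b^2))
  z <- r / d; p <- z; rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    if (sqrt(sum(r^2)) / nb <= tol * 0.5) return(x)
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (sqrt(sum(r^2)) / nb > tol)
    stopf("conjugate gradients did not converge in %d iterations (relative residual %.3g)",
          maxit, sqrt(sum(r^2)) / nb)
  x
}

#' Energy-conservation audit of a converged field
#'
#' Returns the relative imbalance between the heat leaving through the
#' boundaries and the net volumetric sources (metabolic plus perfusion):
#' \eqn{|\sum q_{out} - \sum (Q_{met} + \rho_b C_{p,b}\omega_b (T_b - T)) V| /
#' \max(|\sum sources|, \epsilon)}. For a field solved to a tight residual
#' this is at round-off level; a loosely converged iterative solve shows a
#' visibly larger imbalance.
#'
#' @param field a [solve_steady()] result.
#' @return Relative imbalance (dimensionless).
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
#' energy_balance(solve_steady(g)) < 1e-9
#' @export
energy_balance <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  out <- field$boundary_flux$floor + field$boundary_flux$top
  src <- field$source_total
  # in source-free (pure conduction) problems the gross boundary throughput,
  # not the vanishing net source, sets the meaningful scale
  gross <- abs(field$boundary_flux$floor) + abs(field$boundary_flux$top)
  abs(out - src) / max(abs(src), gross, 1e-12)
}

#' Check the discrete maximum principle
#'
#' The steady solution must lie between the coldest and warmest "anchor"
#' temperatures of the configuration: the floor environment (if convective),
#' the fixed top temperature (if any), and the zero-flux equilibria
#' \eqn{T_b + Q_{met}/(\rho_b C_{p,b} \omega_b)} of every perfused material
#' present. Cells without perfusion only average their neighbours and cannot
#' create extrema.
#'
#' @param field a [solve_steady()] result.
#' @param tol numerical slack in degC.
#' @return `TRUE`/`FALSE`, with attributes `lower`, `upper`, `range`.
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
#' check_max_principle(solve_steady(g))
#' @export
check_max_principle <- function(field, tol = 1e-9) {
  stopifnot(inherits(field, "temperature_field"))
  grid <- field$grid; bc <- field$bc; blood <- field$blood
  present <- sort(unique(as.vector(grid$mat)))
  anchors <- numeric(0)
  for (id in present) {
    m <- grid$materials[[id]]
    if (m$perfusion > 0) {
      P <- blood$density * blood$specific_heat * m$perfusion
      anchors <- c(anchors, m$blood_temperature + m$metabolic_heat / P)
    }
  }
  if (bc$floor_h > 0) anchors <- c(anchors, bc$floor_T_env)
  if (bc$top == "fixed") anchors <- c(anchors, bc$top_temperature)
  lo <- min(anchors); hi <- max(anchors)
  ok <- min(field$T) >= lo - tol && max(field$T) <= hi + tol
  structure(ok, lower = lo, upper = hi, range = range(field$T))
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> %d x %d x %d cells, T in [%.3f, %.3f] degC\n",
              dim(x$T)[1], dim(x$T)[2], dim(x$T)[3], min(x$T), max(x$T)))
  cat(sprintf("  relative residual %.2e; floor outflow %.3f W; sources %.3f W\n",
              x$residual, x$boundary_flux$floor, x$source_total))
  invisible(x)
}

#' @export
summary.temperature_field <- function(object, ...) {
  df <- summarize_field(object)
  cat("Per-material temperature summary (degC):\n")
  print(df, row.names = FALSE, digits = 5)
  invisible(df)
}

#' @export
as.data.frame.temperature_field <- function(x, ...) {
  g <- x$grid
  xc <- cell_centers(g$x_edges); yc <- cell_centers(g$y_edges)
  zc <- cell_centers(g$z_edges)
  data.frame(
    x = rep(xc, times = g$ny * g$nz),
    y = rep(rep(yc, each = g$nx), times = g$nz),
    z = rep(zc, each = g$nx * g$ny),
    material = names(g$materials)[as.vector(g$mat)],
    T = as.vector(x$T))
}

#' Plot a vertical slice of a temperature field
#'
#' @param x a `temperature_field`.
#' @param y unused.
#' @param j lateral y index of the x-z slice (default: mid-plane).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the slice matrix.
#' @export
plot.temperature_field <- function(x, y, j = NULL, ...) {
  g <- x$grid
  if (is.null(j)) j <- max(1L, g$ny %/% 2L)
  slice <- x$T[, j, ]
  image(cell_centers(g$x_edges) * 1e3, cell_centers(g$z_edges) * 1e3,
        slice, col = hcl.colors(64, "Inferno"),
        xlab = "x (mm)", ylab = "depth from deep-tissue face (mm)",
        ylim = rev(range(g$z_edges * 1e3)), ...)
  invisible(slice)
}
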
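# shared fixtures and independent oracles for the test suite

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a narrow laterally-uniform column of the full default stack (fast solves)
column_grid <- function(z_refine = 1L)
  build_domain(foot_insole_layers(), footprint = c(0.008, 0.008),
               dx = 0.004, z_refine = z_refine)

# single-material slab without perfusion (pure conduction checks)
slab_layers <- function(k = 0.5, L = 0.02, n_cells = 8) {
  m <- material_props("slab", 1000, k, 1000)
  list(layer(m, L, n_cells = n_cells, tissue = FALSE))
}

# single perfused muscle block, no insole
muscle_layers <- function(n_cells = 8)
  list(layer(tissue_materials()$muscle, 0.03, n_cells = n_cells, tissue = TRUE))

# independent OLS oracle: closed-form sums, no lm()
ols_sums <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  r2 <- if (sum((y - mean(y))^2) == 0) 0 else
    1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       slope_stderr = sqrt(s2 / sxx), r_squared = r2)
}

# independent brute-force 1-D finite-difference Pennes solve (cell-centred,
# scalar assembly; used oracle-vs-oracle against solve_1d)
fd_pennes_1d <- function(layers, blood = blood_props(), bc = boundary_spec(),
                         n_nodes = 10000) {
  th <- vapply(layers, function(l) l$thickness, 0)
  n_per <- pmax(5L, round(n_nodes * th / sum(th)))
  dz <- rep(th / n_per, n_per)
  lay_of <- rep(seq_along(layers), n_per)
  n <- length(dz)
  k <- vapply(layers, function(l) l$material$conductivity, 0)[lay_of]
  q <- vapply(layers, function(l) l$material$metabolic_heat, 0)[lay_of]
  w <- vapply(layers, function(l) l$material$perfusion, 0)[lay_of]
  tb <- vapply(layers, function(l) l$material$blood_temperature, 0)[lay_of]
  P <- blood$density * blood$specific_heat * w
  tissue <- vapply(layers, `[[`, TRUE, "tissue")
  sock_lay <- if (any(tissue) && any(!tissue)) max(which(tissue)) else 0L
  zc <- cumsum(dz) - dz / 2
  lo <- numeric(n - 1); di <- numeric(n); up <- numeric(n - 1); b <- numeric(n)
  for (i in seq_len(n - 1)) {
    r <- dz[i] / (2 * k[i]) + dz[i + 1] / (2 * k[i + 1])
    if (sock_lay > 0 && lay_of[i] == sock_lay && lay_of[i + 1] == sock_lay + 1L)
      r <- r + bc$sock_resistance
    g <- 1 / r
    di[i] <- di[i] + g; di[i + 1] <- di[i + 1] + g
    lo[i] <- -g; up[i] <- -g
  }
  di <- di + P * dz
  b <- (q + P * tb) * dz
  if (bc$top == "fixed") {
    g <- 2 * k[1] / dz[1]; di[1] <- di[1] + g; b[1] <- b[1] + g * bc$top_temperature
  }
  if (bc$floor_h > 0) {
    g <- if (is.infinite(bc$floor_h)) 2 * k[n] / dz[n]
         else 1 / (dz[n] / (2 * k[n]) + 1 / bc$floor_h)
    di[n] <- di[n] + g; b[n] <- b[n] + g * bc$floor_T_env
  }
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1), diagonals = list(lo, di, up))
  list(z = zc, T = as.numeric(Matrix::solve(A, b)))
}

# scaled-down full detectability sweep, shared by the acceptance tests
# (lateral resolution 4 mm; default z grid; all 26 cases)
acceptance_sweep <- function()
  memo("sweep4mm", run_depth_sweep(sweep_config(dx = 0.004)))

# healthy baseline at the default study resolution (2 mm lateral)
healthy_default <- function()
  memo("healthy_default", {
    t0 <- proc.time()
    f <- solve_steady(build_domain(foot_insole_layers()))
    attr(f, "elapsed_s") <- (proc.time() - t0)[["elapsed"]]
    f
  })
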
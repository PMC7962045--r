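test_that("single unperfused layer with two Dirichlet ends is exactly linear", {
  bc <- boundary_spec(floor_h = Inf, floor_T_env = 20, top = "fixed",
                      top_temperature = 37, sock_resistance = 0)
  sol <- solve_1d(slab_layers(k = 0.5, L = 0.02), bc = bc)
  z <- seq(0, 0.02, length.out = 11)
  expect_equal(predict(sol, z), 37 + (20 - 37) * z / 0.02, tolerance = 1e-10)
  # constant flux k dT/dz
  expect_equal(predict(sol, z, derivative = TRUE),
               rep(0.5 * 17 / 0.02, 11), tolerance = 1e-8)
})

test_that("thick perfused slab approaches the zero-flux equilibrium at depth", {
  # deep end adiabatic; floor convective far away through the slab
  lay <- list(layer(tissue_materials()$muscle, 0.2, n_cells = 3, tissue = TRUE))
  sol <- solve_1d(lay, bc = boundary_spec(sock_resistance = 0))
  teq <- 37 + 684.2 / (1050 * 3617 * 2.7e-3)
  expect_equal(predict(sol, 0), teq, tolerance = 1e-3)   # ~37.07 degC
  expect_equal(teq, 37.07, tolerance = 1e-3)
})

test_that("oracle matches a brute-force finite-difference solve of the full stack", {
  layers <- foot_insole_layers()
  sol <- solve_1d(layers)
  fd <- fd_pennes_1d(layers, n_nodes = 10000)
  expect_lt(max(abs(predict(sol, fd$z) - fd$T)), 1e-4)
})

test_that("oracle satisfies interface continuity and the interior ODE", {
  layers <- foot_insole_layers()
  sol <- solve_1d(layers)
  blood <- blood_props()
  eps <- 1e-9
  tops <- sol$tops[-c(1, length(sol$tops))]
  flux <- function(z) predict(sol, z, derivative = TRUE)
  for (i in seq_along(tops)) {
    # flux continuous at every interface
    expect_equal(flux(tops[i] - eps), flux(tops[i] + eps), tolerance = 1e-5)
    # temperature continuous except across the sock (resistance jump R * q)
    jump <- predict(sol, tops[i] - eps) - predict(sol, tops[i] + eps)
    expected <- if (i == sol$sock_after) 0.02 * flux(tops[i]) else 0
    expect_equal(jump, expected, tolerance = 1e-5)
  }
  # spot-check the ODE residual k T'' + P (Tb - T) + Q = 0 by central
  # differences inside the perfused layers (where the equation has content;
  # in source-free layers the check degenerates to differencing noise)
  set.seed(42)
  perf <- which(vapply(layers, function(l) l$material$perfusion > 0, TRUE))
  for (rep in 1:10) {
    li <- sample(perf, 1)
    m <- layers[[li]]$material
    h <- layers[[li]]$thickness / 20
    z <- sol$tops[li] + runif(1, 0.2, 0.8) * layers[[li]]$thickness
    d2 <- (predict(sol, z + h) - 2 * predict(sol, z) + predict(sol, z - h)) / h^2
    P <- blood$density * blood$specific_heat * m$perfusion
    resid <- m$conductivity * d2 + P * (m$blood_temperature - predict(sol, z)) +
      m$metabolic_heat
    scale <- max(abs(m$conductivity * d2), abs(P * 20), m$metabolic_heat)
    expect_lt(abs(resid) / scale, 1e-3)
  }
})

test_that("degenerate 1-D configurations are rejected", {
  expect_error(solve_1d(slab_layers(),
                        bc = boundary_spec(floor_h = 0, sock_resistance = 0)),
               "anchor|degenerate")
})

test_that("3-D solver agrees with the oracle and converges at second order", {
  sol <- solve_1d(foot_insole_layers())
  f1 <- solve_steady(column_grid(1L))
  f2 <- solve_steady(column_grid(2L))
  d1 <- as.numeric(compare_to_oracle(f1, sol))
  d2 <- as.numeric(compare_to_oracle(f2, sol))
  expect_lt(d1, 0.01)          # default z grid within 0.01 degC of closed form
  expect_gt(d1 / d2, 2.5)      # halving dz shrinks the error ~4x
  # comparing a configuration against itself is exact
  expect_equal(d2, as.numeric(compare_to_oracle(f2, sol)))
  # mismatched stacks are detected
  expect_error(compare_to_oracle(f1, solve_1d(slab_layers())), "differ")
})
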
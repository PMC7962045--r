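test_that("pure conduction reproduces the linear profile and its flux", {
  k <- 0.5; L <- 0.02
  g <- build_domain(slab_layers(k = k, L = L, n_cells = 10),
                    footprint = c(0.02, 0.02), dx = 0.01)
  bc <- boundary_spec(floor_h = Inf, floor_T_env = 20, top = "fixed",
                      top_temperature = 37, sock_resistance = 0)
  f <- solve_steady(g, bc = bc)
  zc <- (g$z_edges[-1] + g$z_edges[-length(g$z_edges)]) / 2
  lin <- 37 + (20 - 37) * zc / L
  expect_equal(as.vector(f$T[1, 1, ]), lin, tolerance = 1e-10)
  area <- 0.02 * 0.02
  expect_equal(f$boundary_flux$floor, k * 17 / L * area, tolerance = 1e-8)
  expect_lt(energy_balance(f), 1e-10)
})

test_that("all-adiabatic perfused block settles at the zero-flux equilibrium", {
  g <- build_domain(muscle_layers(), footprint = c(0.02, 0.02), dx = 0.01)
  bc <- boundary_spec(floor_h = 0, sock_resistance = 0)
  f <- solve_steady(g, bc = bc)
  teq <- 37 + 684.2 / (1050 * 3617 * 2.7e-3)   # Tb + Qmet / (rho_b Cp_b omega_b)
  expect_equal(teq, 37.0667, tolerance = 1e-5)  # ~0.067 degC above Tb
  expect_equal(as.vector(f$T), rep(teq, length(f$T)), tolerance = 1e-9)
})

test_that("a fully adiabatic unperfused system is rejected as singular", {
  g <- build_domain(slab_layers(), footprint = c(0.02, 0.02), dx = 0.01)
  expect_error(solve_steady(g, bc = boundary_spec(floor_h = 0, sock_resistance = 0)),
               "anchor")
})

test_that("solution is linear in a uniform shift of all anchor temperatures", {
  g <- column_grid()
  f1 <- solve_steady(g)
  shift_mats <- lapply(foot_insole_layers(), function(l) {
    l$material$blood_temperature <- l$material$blood_temperature + 1
    l
  })
  g2 <- build_domain(shift_mats, footprint = c(0.008, 0.008), dx = 0.004)
  f2 <- solve_steady(g2, bc = boundary_spec(floor_T_env = 21))
  expect_equal(max(abs(f2$T - f1$T - 1)), 0, tolerance = 1e-8)
})

test_that("sock contact resistance strictly reduces interface heat flux", {
  g <- column_grid()
  f_sock <- solve_steady(g, bc = boundary_spec(sock_resistance = 0.02))
  f_bare <- solve_steady(g, bc = boundary_spec(sock_resistance = 0))
  # steady 1-D: floor outflow equals the flux crossing the skin-insole interface
  expect_lt(f_sock$boundary_flux$floor, f_bare$boundary_flux$floor)
  # and the insole surface runs cooler under the sock
  expect_lt(surface_mean_temperature(f_sock, "insole_top"),
            surface_mean_temperature(f_bare, "insole_top"))
})

test_that("energy balance closes at round-off for converged solves", {
  f <- solve_steady(column_grid())
  expect_lt(energy_balance(f), 1e-6)
  expect_lt(f$residual, 1e-10)
  # conjugate-gradient route agrees with the direct solve
  fc <- solve_steady(column_grid(), method = "cg", tol = 1e-5)
  expect_lt(max(abs(fc$T - f$T)), 1e-3)
  expect_error(solve_steady(column_grid(), method = "cg", tol = 1e-5, maxit = 3L),
               "converge")
})

test_that("discrete maximum principle holds on the healthy stack", {
  f <- solve_steady(column_grid())
  ok <- check_max_principle(f)
  expect_true(as.logical(ok))
  expect_gte(min(f$T), 20 - 1e-9)                      # floor environment
  expect_lte(max(f$T), attr(ok, "upper") + 1e-9)       # warmest perfused equilibrium
})

test_that("solution has no preferred lateral origin (mirror symmetry)", {
  # placing the lesion at x0 or mirrored about the domain mid-plane must give
  # mirror-image fields to round-off: no hidden dependence on absolute position
  mk <- function(ctr) {
    g <- build_domain(foot_insole_layers(), footprint = c(0.06, 0.04), dx = 0.004)
    solve_steady(embed_lesion(g, lesion_spec("inflammation", 2.6e-3, center = ctr)))
  }
  f1 <- mk(c(0.022, 0.018))
  f2 <- mk(c(0.06 - 0.022, 0.018))
  nx <- dim(f1$T)[1]
  # fill-reducing ordering is not mirror-symmetric, so agreement is at the
  # level of solver round-off, far below any physical signal
  expect_lt(max(abs(f2$T[nx:1, , ] - f1$T)), 1e-6)
})

test_that("perturbed tissue parameter sets keep the solution physical", {
  base <- tissue_materials()
  mk_layers <- function(mats) list(
    layer(mats$muscle, 25e-3, n_cells = 6, grading = 0.7, tissue = TRUE),
    layer(mats$fat, 5e-3, n_cells = 3, tissue = TRUE),
    layer(mats$epidermis, 0.46e-3, n_cells = 3, tissue = TRUE),
    layer(insole_materials()$polyurethane, 4e-3, n_cells = 3),
    layer(insole_materials()$rubber, 15e-3, n_cells = 3))
  temps <- vapply(1:20, function(i) {
    mats <- perturb_tissue_params(base, 0.1, seed = 1000 + i)
    g <- build_domain(mk_layers(mats), footprint = c(0.008, 0.008), dx = 0.004)
    f <- solve_steady(g)
    expect_true(as.logical(check_max_principle(f)),
                info = sprintf("perturbation seed %d", 1000 + i))
    summarize_field(f)$mean_T[1]
  }, 0)
  # muscle temperature responds smoothly: modest spread under 10% jitter
  expect_lt(diff(range(temps)), 1)
})
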
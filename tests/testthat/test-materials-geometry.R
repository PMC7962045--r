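test_that("material constructors validate physical invariants", {
  expect_error(material_props("x", -1, 0.5, 1000), "density")
  expect_error(material_props("x", 1000, 0, 1000), "conductivity")
  expect_error(material_props("x", 1000, 0.5, 1000, metabolic_heat = -1),
               "metabolic_heat")
  expect_error(material_props("x", 1000, 0.5, 1000, perfusion = -0.1),
               "perfusion")
  expect_error(blood_props(density = 0), "density")
  m <- tissue_materials()
  expect_identical(m$epidermis$perfusion, 0)
  expect_identical(m$ischemia$blood_temperature, 35)
  expect_true(all(vapply(insole_materials(), function(x)
    x$perfusion == 0 && x$metabolic_heat == 0, TRUE)))
})

test_that("tissue interfaces land on the cumulative printed thicknesses", {
  g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
  # depths below the plantar skin surface of the tissue interfaces
  expected_mm <- cumsum(c(0.46, 1.67, 1.67, 5, 25))   # epidermis -> muscle top
  depth_mm <- (g$skin_depth - g$z_edges) * 1e3
  for (d in expected_mm)
    expect_true(any(abs(depth_mm - d) < 1e-9), info = sprintf("interface %g mm", d))
  # insole sub-layers: 1, 0.36, 0.018, 3 mm plus 15 mm rubber below
  ins <- vapply(g$layers[!vapply(g$layers, `[[`, TRUE, "tissue")],
                `[[`, 0, "thickness") * 1e3
  expect_equal(ins, c(1, 0.36, 0.018, 3, 15))
  expect_equal(g$skin_depth, 33.8e-3, tolerance = 1e-12)
})

test_that("grid lines reproduce layer thicknesses exactly, >= 3 cells per layer", {
  g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
  dz <- diff(g$z_edges)
  per_layer <- vapply(seq_along(g$layers), function(i) sum(dz[g$layer_id == i]), 0)
  expect_equal(per_layer,
               vapply(g$layers, `[[`, 0, "thickness"), tolerance = 1e-12)
  expect_true(all(table(g$layer_id) >= 3))
  expect_true(all(diff(g$z_edges) > 0))
  # refinement preserves interfaces and multiplies cell counts
  g2 <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02),
                     dx = 0.01, z_refine = 2L)
  expect_equal(g2$nz, 2L * g$nz)
  expect_true(all(g$z_edges %in% g2$z_edges))
})

test_that("degenerate and invalid domain configurations are rejected", {
  one <- slab_layers()
  g <- build_domain(one, footprint = c(0.02, 0.02), dx = 0.01)
  expect_identical(length(unique(as.vector(g$mat))), 1L)   # single material id
  expect_error(layer(tissue_materials()$fat, 0), "thickness")
  expect_error(build_domain(one, footprint = c(0.005, 0.02), dx = 0.01),
               "2 lateral cells")
  expect_error(build_domain(list(), footprint = c(0.02, 0.02)), "layers")
})

test_that("lesion ellipsoid matches the printed height and volume constraints", {
  les <- lesion_spec("inflammation", 2.6e-3, center = c(0.01, 0.01))
  expect_equal(les$c_semi, 1.25e-3)
  expect_equal(les$a_semi, sqrt(1.5e-6 / (4 / 3 * pi * 1.25e-3)), tolerance = 1e-12)
  expect_equal(les$a_semi, 16.93e-3, tolerance = 1e-3)
  # volume inconsistent with height (a < c) is rejected
  expect_error(lesion_spec("inflammation", 2.6e-3, height = 20e-3,
                           volume = 1e-8, center = c(0.01, 0.01)), "inconsistent")
})

test_that("embed_lesion reassigns the right cells and is idempotent", {
  g <- build_domain(foot_insole_layers(), footprint = c(0.08, 0.08), dx = 0.004)
  ctr <- c(0.04, 0.04)
  les <- lesion_spec("inflammation", 2.6e-3, center = ctr)
  g1 <- embed_lesion(g, les)
  expect_gt(g1$lesion$n_cells, 0)
  # voxelized volume within 10% of the analytic 1.5 cm3
  expect_lt(abs(g1$lesion$voxel_volume / 1.5e-6 - 1), 0.10)
  # reassigned cells span approximately centre +- c (1.35 to 3.85 mm deep)
  zc <- (g$z_edges[-1] + g$z_edges[-length(g$z_edges)]) / 2
  kk <- which(apply(g1$mat != g$mat, 3, any))
  depth_mm <- (g1$skin_depth - zc[kk]) * 1e3
  expect_true(all(depth_mm > 1.35 - 0.5 & depth_mm < 3.85 + 0.5))
  # idempotent
  g2 <- embed_lesion(g1, les)
  expect_identical(g2$mat, g1$mat)
  # zero volume is a no-op
  expect_identical(embed_lesion(g, lesion_spec("inflammation", 2.6e-3,
                                               volume = 0, center = ctr))$mat,
                   g$mat)
  # out-of-footprint centre rejected
  expect_error(embed_lesion(g, lesion_spec("ischemia", 2.6e-3,
                                           center = c(0.5, 0.04))), "footprint")
})

test_that("voxelized lesion volume converges to the analytic volume", {
  ctr <- c(0.04, 0.04)
  les <- lesion_spec("inflammation", 2.6e-3, center = ctr)
  err <- vapply(c(1L, 2L, 4L), function(rf) {
    g <- build_domain(foot_insole_layers(), footprint = c(0.08, 0.08),
                      dx = 0.004 / rf, z_refine = rf)
    abs(embed_lesion(g, les)$lesion$voxel_volume / 1.5e-6 - 1)
  }, 0)
  expect_lt(err[3], err[1])    # finer grid, smaller volume error
  expect_lt(err[3], 0.02)
})

test_that("sensor layout scales with foot length and accepts overrides", {
  lay <- default_sensor_layout(0.247)
  expect_identical(nrow(lay), 8L)
  expect_true(all(lay$x >= 0 & lay$x <= 0.247))
  expect_identical(attr(lay, "threshold"), 0.1)
  lay2 <- default_sensor_layout(0.247 * 1.2)
  expect_equal(lay2$x, lay$x * 1.2, tolerance = 1e-12)
  # verbatim override
  pos <- data.frame(sensor = paste0("S", 1:8), x = seq(0.01, 0.08, 0.01), y = 0.05)
  expect_equal(default_sensor_layout(positions = pos)$x, pos$x)
  expect_error(default_sensor_layout(0.4), "foot_length")
  expect_error(default_sensor_layout(0.1), "foot_length")
})
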
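#' Thermophysical material properties
#'
#' A material carries the volumetric thermophysical parameters of the Pennes
#' bioheat model: density \eqn{\rho} (kg/m3), thermal conductivity \eqn{k}
#' (W/m/K), specific heat \eqn{C_p} (J/kg/K), metabolic volumetric heat source
#' \eqn{Q_{met}} (W/m3), blood perfusion rate \eqn{\omega_b} (1/s) and the
#' arterial blood temperature \eqn{T_b} (degC) that perfusion pulls the tissue
#' towards. Non-biological materials (insole and shoe layers) must have zero
#' metabolic heat and zero perfusion.
#'
#' @param name label for the material.
#' @param density density in kg/m3 (> 0).
#' @param conductivity thermal conductivity in W/m/K (> 0).
#' @param specific_heat specific heat capacity in J/kg/K (> 0).
#' @param metabolic_heat volumetric metabolic heat source in W/m3 (>= 0).
#' @param perfusion blood perfusion rate in 1/s (>= 0).
#' @param blood_temperature arterial blood temperature in degC (used only
#'   when `perfusion > 0`).
#' @return An object of class `material_props`.
#' @examples
#' material_props("muscle", 1085, 0.51, 3600,
#'                metabolic_heat = 684.2, perfusion = 2.7e-3)
#' @export
material_props <- function(name, density, conductivity, specific_heat,
                           metabolic_heat = 0, perfusion = 0,
                           blood_temperature = 37) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("`name` must be a non-empty string")
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  check_number(conductivity, "conductivity", lower = 0, strict_lower = TRUE)
  check_number(specific_heat, "specific_heat", lower = 0, strict_lower = TRUE)
  check_number(metabolic_heat, "metabolic_heat", lower = 0)
  check_number(perfusion, "perfusion", lower = 0)
  check_number(blood_temperature, "blood_temperature")
  structure(
    list(name = name, density = density, conductivity = conductivity,
         specific_heat = specific_heat, metabolic_heat = metabolic_heat,
         perfusion = perfusion, blood_temperature = blood_temperature),
    class = "material_props")
}

#' @export
print.material_props <- function(x, ...) {
  cat(sprintf("<material_props> %s\n", x$name))
  cat(sprintf("  rho = %g kg/m3, k = %g W/m/K, Cp = %g J/kg/K\n",
              x$density, x$conductivity, x$specific_heat))
  if (x$perfusion > 0 || x$metabolic_heat > 0)
    cat(sprintf("  Qmet = %g W/m3, omega_b = %g 1/s, Tb = %g degC\n",
                x$metabolic_heat, x$perfusion, x$blood_temperature))
  invisible(x)
}

#' Blood properties of the perfusion term
#'
#' Density and specific heat of arterial blood entering the Pennes sink term
#' \eqn{\rho_b C_{p,b} \omega_b (T_b - T)}. The defaults, 1050 kg/m3 and
#' 3617 J/kg/K, are standard human-blood values; they matter because the
#' zero-flux tissue equilibrium is
#' \eqn{T_b + Q_{met}/(\rho_b C_{p,b} \omega_b)}.
#'
#' @param density blood density in kg/m3 (> 0).
#' @param specific_heat blood specific heat in J/kg/K (> 0).
#' @return An object of class `blood_props`.
#' @examples
#' blood_props()
#' @export
blood_props <- function(density = 1050, specific_heat = 3617) {
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  check_number(specific_heat, "specific_heat", lower = 0, strict_lower = TRUE)
  structure(list(density = density, specific_heat = specific_heat),
            class = "blood_props")
}

#' @export
print.blood_props <- function(x, ...) {
  cat(sprintf("<blood_props> rho_b = %g kg/m3, Cp_b = %g J/kg/K\n",
              x$density, x$specific_heat))
  invisible(x)
}

#' Reference tissue materials
#'
#' The five plantar tissue layers (epidermis, papillary dermis, reticular
#' dermis, fat, muscle) and the two lesion tissues (inflammation, ischemia)
#' with their published thermophysical properties. Arterial blood is at
#' 37 degC for every tissue except the ischemic lesion (35 degC).
#'
#' @return Named list of [material_props()] objects.
#' @examples
#' names(tissue_materials())
#' tissue_materials()$muscle
#' @export
tissue_materials <- function() {
  list(
    epidermis = material_props("epidermis", 1200, 0.235, 3589,
                               metabolic_heat = 0, perfusion = 0),
    papillary_dermis = material_props("papillary_dermis", 1200, 0.445, 3300,
                                      metabolic_heat = 368.1, perfusion = 0.18e-3),
    reticular_dermis = material_props("reticular_dermis", 1200, 0.445, 3300,
                                      metabolic_heat = 368.1, perfusion = 1.26e-3),
    fat = material_props("fat", 1000, 0.185, 2674,
                         metabolic_heat = 368.3, perfusion = 0.08e-3),
    muscle = material_props("muscle", 1085, 0.51, 3600,
                            metabolic_heat = 684.2, perfusion = 2.7e-3),
    inflammation = material_props("inflammation", 1037, 0.558, 2450,
                                  metabolic_heat = 5262.5, perfusion = 6.95e-3),
    ischemia = material_props("ischemia", 1037, 0.1, 2450,
                              metabolic_heat = 342.1, perfusion = 0.405e-3,
                              blood_temperature = 35))
}

#' Reference insole and shoe materials
#'
#' Antibacterial polyurethane (insole body), kapton (flexible circuit
#' carrier), copper (circuit board) and shoe rubber, with zero perfusion and
#' metabolic heat.
#'
#' @return Named list of [material_props()] objects.
#' @examples
#' insole_materials()$polyurethane
#' @export
insole_materials <- function() {
  list(
    polyurethane = material_props("polyurethane", 374, 0.06, 1337),
    kapton = material_props("kapton", 1300, 0.15, 1100),
    copper = material_props("copper", 8960, 401, 384),
    rubber = material_props("rubber", 1100, 0.13, 2010))
}

#' Define one layer of the vertical stack
#'
#' @param material a [material_props()] object.
#' @param thickness layer thickness in m (> 0).
#' @param n_cells number of grid cells across the layer (>= 3); default picks
#'   `max(3, ceiling(thickness / 1 mm))` capped at 12.
#' @param grading geometric cell-size ratio applied downward through the
#'   layer: 1 gives uniform cells, values below 1 refine toward the layer's
#'   lower face.
#' @param tissue logical: is this a perfusable biological layer (part of the
#'   foot) rather than insole/shoe material? Controls where the sock contact
#'   resistance and the lesion sub-domain live.
#' @return An object of class `layer_spec`.
#' @examples
#' layer(tissue_materials()$fat, 5e-3)
#' @export
layer <- function(material, thickness, n_cells = NULL, grading = 1,
                  tissue = material$perfusion > 0 || material$metabolic_heat > 0) {
  if (!inherits(material, "material_props"))
    stopf("`material` must be a material_props object")
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  if (is.null(n_cells)) n_cells <- min(12L, max(3L, ceiling(thickness / 1e-3)))
  n_cells <- as.integer(n_cells)
  if (n_cells < 3L) stopf("each layer must span at least 3 cells")
  check_number(grading, "grading", lower = 0, strict_lower = TRUE)
  structure(list(material = material, thickness = thickness,
                 n_cells = n_cells, grading = grading, tissue = isTRUE(tissue)),
            class = "layer_spec")
}

#' Default foot + insole + shoe layer stack
#'
#' Returns the vertical stack, listed from the deep (proximal) end down to
#' the floor: muscle (25 mm), fat (5 mm), reticular dermis (1.67 mm),
#' papillary dermis (1.67 mm), epidermis (0.46 mm), then the insole - upper
#' polyurethane (1 mm), kapton (0.36 mm), copper (0.018 mm), bottom
#' polyurethane (3 mm) - and a 15 mm rubber shoe sole. The muscle layer uses
#' a geometrically graded grid, finest at its distal face where lesions sit
#' and where the perfusion boundary layer (about 7 mm) must be resolved.
#'
#' @param include_insole include the four insole sub-layers.
#' @param include_shoe include the rubber shoe sole (requires the insole).
#' @return List of [layer()] objects, top first.
#' @examples
#' length(foot_insole_layers())
#' @export
foot_insole_layers <- function(include_insole = TRUE, include_shoe = TRUE) {
  tis <- tissue_materials(); ins <- insole_materials()
  stack <- list(
    layer(tis$muscle, 25e-3, n_cells = 12, grading = 0.78, tissue = TRUE),
    layer(tis$fat, 5e-3, n_cells = 6, tissue = TRUE),
    layer(tis$reticular_dermis, 1.67e-3, n_cells = 3, tissue = TRUE),
    layer(tis$papillary_dermis, 1.67e-3, n_cells = 3, tissue = TRUE),
    layer(tis$epidermis, 0.46e-3, n_cells = 3, tissue = TRUE))
  if (include_insole) {
    stack <- c(stack, list(
      layer(ins$polyurethane, 1e-3, n_cells = 3),
      layer(ins$kapton, 0.36e-3, n_cells = 3),
      layer(ins$copper, 0.018e-3, n_cells = 3),
      layer(ins$polyurethane, 3e-3, n_cells = 4)))
    if (include_shoe)
      stack <- c(stack, list(layer(ins$rubber, 15e-3, n_cells = 5)))
  }
  stack
}
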
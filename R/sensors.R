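#' Default eight-point insole sensor layout
#'
#' Positions of the eight temperature sensing points on the insole top
#' surface, scaled linearly with foot length: hallux (S1), three metatarsal
#' heads (S2-S4), lateral midfoot (S5), medial arch (S6) and two heel points
#' (S7, S8). The published layout is schematic, so the coordinates are
#' fractional approximations of it; they can be overridden verbatim via
#' `positions`. x runs from the heel (0) to the toes.
#'
#' @param foot_length foot length in m, within `[0.20, 0.32]` (insole sizes
#'   around european 39-42 correspond to 0.247-0.267 m).
#' @param foot_width insole width in m; y coordinates scale with it.
#' @param threshold detection threshold in degC (default 0.1, the resolution
#'   of the readout device).
#' @param positions optional data.frame with columns `sensor`, `x`, `y` (m),
#'   returned as supplied.
#' @return A `sensor_layout`: data.frame of `sensor`, `x`, `y` with
#'   attributes `threshold`, `foot_length`, `foot_width`.
#' @examples
#' default_sensor_layout(0.247)
#' @export
default_sensor_layout <- function(foot_length = 0.26, foot_width = 0.09,
                                  threshold = 0.1, positions = NULL) {
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  if (is.null(positions)) {
    check_number(foot_length, "foot_length", lower = 0.20, upper = 0.32)
    check_number(foot_width, "foot_width", lower = 0, strict_lower = TRUE)
    frac <- data.frame(
      sensor = paste0("S", 1:8),
      fx = c(0.88, 0.72, 0.70, 0.70, 0.56, 0.45, 0.18, 0.12),
      fy = c(0.35, 0.24, 0.50, 0.70, 0.72, 0.35, 0.60, 0.45))
    positions <- data.frame(sensor = frac$sensor,
                            x = frac$fx * foot_length,
                            y = frac$fy * foot_width)
  } else {
    if (!is.data.frame(positions) ||
        !all(c("sensor", "x", "y") %in% names(positions)))
      stopf("`positions` must be a data.frame with columns sensor, x, y")
    positions <- positions[, c("sensor", "x", "y")]
  }
  structure(positions, threshold = threshold,
            foot_length = foot_length, foot_width = foot_width,
            class = c("sensor_layout", "data.frame"))
}

#' Sample a temperature field at the sensor positions
#'
#' Reads the temperature of the insole top-surface cell nearest to each
#' sensor's `(x, y)`: the via hole under each sensing pad is filled with
#' conductive paste, thermally shorting the pad to the insole contact
#' surface, so the read plane is the top cell of the upper insole layer
#' (the bottom tissue cell if the grid has no insole). The nearest-cell rule
#' is deterministic, ties breaking toward the lower cell index.
#'
#' @param field a [solve_steady()] result.
#' @param layout a [default_sensor_layout()].
#' @return data.frame with `sensor`, `x`, `y` (cell-centre position used)
#'   and `T` (degC).
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.26, 0.09), dx = 0.02)
#' f <- solve_steady(g)
#' read_sensors(f, default_sensor_layout())
#' @export
read_sensors <- function(field, layout) {
  stopifnot(inherits(field, "temperature_field"))
  g <- field$grid
  if (any(layout$x < 0 | layout$x > g$footprint[1] |
          layout$y < 0 | layout$y > g$footprint[2]))
    stopf("sensor position outside the domain footprint")
  tissue_k <- vapply(g$layer_id, function(i) g$layers[[i]]$tissue, TRUE)
  k_surf <- if (any(!tissue_k)) which(!tissue_k)[1L] else g$nz
  xc <- cell_centers(g$x_edges); yc <- cell_centers(g$y_edges)
  i <- vapply(layout$x, function(p) which.min(abs(xc - p)), 0L)
  j <- vapply(layout$y, function(p) which.min(abs(yc - p)), 0L)
  data.frame(sensor = layout$sensor, x = xc[i], y = yc[j],
             T = field$T[cbind(i, j, k_surf)])
}

#' Detectability of a temperature deviation
#'
#' A sensor flags a lesion when the absolute deviation from the matched
#' healthy baseline reaches the readout resolution; the comparison is
#' inclusive (a deviation exactly at threshold is the smallest detectable
#' change). Ischemic lesions cool the surface, so the absolute value
#' matters.
#'
#' @param delta temperature deviation(s) in degC.
#' @param threshold detection threshold in degC (> 0).
#' @return Logical vector.
#' @examples
#' classify_detectable(c(0.15, 0, -0.1), 0.1)
#' @export
classify_detectable <- function(delta, threshold = 0.1) {
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  abs(delta) >= threshold
}

#' Per-sensor temperature deviation between a lesion case and its baseline
#'
#' Both fields must come from the same grid discretization and boundary
#' conditions (including the sock setting), differing only in lesion
#' presence, so the deviation is free of discretization noise.
#'
#' @param lesion_field,healthy_field matched [solve_steady()] results.
#' @param layout a [default_sensor_layout()].
#' @param threshold detection threshold in degC; defaults to the layout's.
#' @return data.frame with `sensor`, `T_lesion`, `T_healthy`, `delta`
#'   (lesion minus healthy, degC) and `detectable`.
#' @export
sensor_deltas <- function(lesion_field, healthy_field, layout,
                          threshold = attr(layout, "threshold")) {
  stopifnot(inherits(lesion_field, "temperature_field"),
            inherits(healthy_field, "temperature_field"))
  if (!identical(dim(lesion_field$T), dim(healthy_field$T)))
    stopf("fields come from different grids")
  if (!isTRUE(all.equal(lesion_field$bc, healthy_field$bc)))
    stopf("fields were solved under different boundary conditions")
  les <- read_sensors(lesion_field, layout)
  hea <- read_sensors(healthy_field, layout)
  data.frame(sensor = les$sensor, T_lesion = les$T, T_healthy = hea$T,
             delta = les$T - hea$T,
             detectable = classify_detectable(les$T - hea$T, threshold))
}
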
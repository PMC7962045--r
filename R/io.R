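#' Read a simulation configuration file
#'
#' Parses a YAML configuration with sections `grid`, `layers`, `blood`,
#' `boundary`, `lesion` and `sensors` into a [sweep_config()]. Layer entries
#' either name a built-in material (`material: muscle`) or give the full
#' property set; thicknesses are in mm when the file declares
#' `units: {thickness: mm}` (the default) and in m otherwise. Unknown keys
#' anywhere raise an error rather than being silently ignored.
#'
#' @param path path to a YAML file; see
#'   `system.file("extdata", "default_sweep.yaml", package = "soleheat")`.
#' @return A [sweep_config()].
#' @examples
#' cfg <- read_sim_config(system.file("extdata", "default_sweep.yaml",
#'                                    package = "soleheat"))
#' cfg$depths
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- c("units", "grid", "layers", "blood", "boundary", "lesion", "sensors")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stopf("unknown config section(s): %s", paste(extra, collapse = ", "))

  th_unit <- 1e-3
  if (!is.null(raw$units)) {
    check_keys(raw$units, c("thickness"), "units")
    if (!is.null(raw$units$thickness))
      th_unit <- switch(raw$units$thickness, mm = 1e-3, m = 1,
                        stopf("units$thickness must be 'mm' or 'm'"))
  }

  builtin <- c(tissue_materials(), insole_materials())
  layers <- lapply(raw$layers, function(l) {
    check_keys(l, c("material", "thickness", "n_cells", "grading", "tissue",
                    "name", "density", "conductivity", "specific_heat",
                    "metabolic_heat", "perfusion", "blood_temperature"),
               "layers entry")
    mat <- if (!is.null(l$material)) {
      if (is.null(builtin[[l$material]]))
        stopf("unknown built-in material '%s'", l$material)
      builtin[[l$material]]
    } else {
      material_props(l$name, l$density, l$conductivity, l$specific_heat,
                     metabolic_heat = l$metabolic_heat %||% 0,
                     perfusion = l$perfusion %||% 0,
                     blood_temperature = l$blood_temperature %||% 37)
    }
    args <- list(material = mat, thickness = l$thickness * th_unit)
    if (!is.null(l$n_cells)) args$n_cells <- l$n_cells
    if (!is.null(l$grading)) args$grading <- l$grading
    args$tissue <- l$tissue %||%
      (!is.null(l$material) && l$material %in% names(tissue_materials()))
    do.call(layer, args)
  })

  g <- raw$grid %||% list()
  check_keys(g, c("footprint", "dx", "z_refine"), "grid")
  b <- raw$blood %||% list()
  check_keys(b, c("density", "specific_heat"), "blood")
  bd <- raw$boundary %||% list()
  check_keys(bd, c("floor_h", "floor_T_env", "sock_resistance", "sock"), "boundary")
  le <- raw$lesion %||% list()
  check_keys(le, c("depths", "types", "height", "volume", "center"), "lesion")
  se <- raw$sensors %||% list()
  check_keys(se, c("threshold", "positions", "foot_length", "foot_width"), "sensors")

  layout <- NULL
  if (!is.null(se$positions)) {
    pos <- do.call(rbind, lapply(se$positions, function(p)
      data.frame(sensor = p$sensor, x = p$x, y = p$y)))
    layout <- default_sensor_layout(threshold = se$threshold %||% 0.1,
                                    positions = pos)
  }
  sweep_config(
    depths = (le$depths %||% c(1.6, 2.6, 3.4, 5.9, 8.4, 9.7)) * th_unit,
    types = unlist(le$types %||% c("inflammation", "ischemia")),
    sock = bd$sock %||% c(TRUE, FALSE),
    layers = layers,
    footprint = unlist(g$footprint %||% c(0.26, 0.09)),
    dx = g$dx %||% 0.002,
    z_refine = g$z_refine %||% 1L,
    blood = blood_props(b$density %||% 1050, b$specific_heat %||% 3617),
    floor_h = bd$floor_h %||% 5,
    floor_T_env = bd$floor_T_env %||% 20,
    sock_resistance = bd$sock_resistance %||% 0.02,
    layout = layout,
    lesion_center = if (!is.null(le$center)) unlist(le$center),
    lesion_height = (le$height %||% 2.5) * th_unit,
    lesion_volume = le$volume %||% 1.5e-6,
    threshold = se$threshold %||% 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stopf("unknown key(s) in %s: %s", where, paste(extra, collapse = ", "))
  invisible(x)
}

#' Write the detection report to CSV
#'
#' One row per lesion case: case id, lesion type, depth, sock flag, the
#' per-sensor temperature deviations (degC, 3 decimals) and detectability
#' flags. The file is written atomically (temp file then rename) and a
#' comment line records the configuration fingerprint.
#'
#' @param report a [run_depth_sweep()] result.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "detection_report"))
  d <- report$cases
  num <- vapply(d, is.numeric, TRUE) & !(names(d) %in% c("depth_mm", "residual"))
  d[num] <- lapply(d[num], round, digits = 3)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(sprintf("# soleheat detection report; config fingerprint %s",
                       report$fingerprint), con)
    write.csv(d, con, row.names = FALSE)
  })
}

#' Export a temperature field
#'
#' `write_field_csv()` writes one row per cell (centre coordinates in m,
#' material, temperature in degC). `write_field_vtk()` writes a legacy
#' ASCII VTK rectilinear grid with cell-centred temperature and material
#' id, loadable in ParaView for visual inspection of the thermal maps.
#' Both writes are atomic.
#'
#' @param field a [solve_steady()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  df <- as.data.frame(field)
  df$T <- round(df$T, 3)
  atomic_write(path, function(tmp) write.csv(df, tmp, row.names = FALSE))
}

#' @rdname write_field_csv
#' @export
write_field_vtk <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  g <- field$grid
  fmt <- function(x) paste(sprintf("%.9g", x), collapse = " ")
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "soleheat steady-state temperature field",
                 "ASCII", "DATASET RECTILINEAR_GRID",
                 sprintf("DIMENSIONS %d %d %d", g$nx + 1L, g$ny + 1L, g$nz + 1L),
                 sprintf("X_COORDINATES %d double", g$nx + 1L), fmt(g$x_edges),
                 sprintf("Y_COORDINATES %d double", g$ny + 1L), fmt(g$y_edges),
                 sprintf("Z_COORDINATES %d double", g$nz + 1L), fmt(-g$z_edges),
                 sprintf("CELL_DATA %d", g$nx * g$ny * g$nz),
                 "SCALARS temperature double 1", "LOOKUP_TABLE default",
                 fmt(as.vector(field$T)),
                 "SCALARS material int 1", "LOOKUP_TABLE default",
                 paste(as.vector(g$mat), collapse = " ")), con)
  })
}

#' Read and write two-column measurement tables
#'
#' Delimited-text format shared by the calibration readers and the
#' synthetic generators: `# key: value` header lines carrying metadata,
#' then a CSV header and the data columns. [write_xy_table()] round-trips
#' the attributes of generator outputs; [read_trace()] restores a `cv_trace`
#' (scan parameters included) so peak extraction works on files exactly as
#' on in-memory traces.
#'
#' @param x data.frame to write (e.g. [gen_charge_force()] or
#'   [gen_cv_trace()] output).
#' @param path file path.
#' @param meta named list of metadata to store in `#` header lines;
#'   defaults to the scalar attributes of `x`.
#' @return `read_xy_table()`: data.frame with metadata in attributes;
#'   `read_trace()`: a `cv_trace`. Writers return the path invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_xy_table(gen_charge_force(5, seed = 1), p)
#' read_xy_table(p)
#' @export
write_xy_table <- function(x, path, meta = NULL) {
  if (is.null(meta)) {
    at <- attributes(x)
    at <- at[!(names(at) %in% c("names", "row.names", "class"))]
    meta <- Filter(function(v) is.atomic(v) && length(v) <= 8 && !is.null(v), at)
  }
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    for (nm in names(meta))
      writeLines(sprintf("# %s: %s", nm,
                         paste(format(meta[[nm]], digits = 15), collapse = ",")), con)
    write.csv(as.data.frame(x), con, row.names = FALSE)
  })
}

#' @rdname write_xy_table
#' @export
read_xy_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[h]))[[1]]
    if (length(m) == 3) {
      vals <- strsplit(m[3], ",", fixed = TRUE)[[1]]
      num <- suppressWarnings(as.numeric(vals))
      meta[[trimws(m[2])]] <- if (!any(is.na(num))) num else trimws(m[3])
    }
  }
  df <- read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                              collapse = "\n"))
  for (nm in names(meta)) attr(df, nm) <- meta[[nm]]
  df
}

#' @rdname write_xy_table
#' @export
read_trace <- function(path) {
  df <- read_xy_table(path)
  if (!all(c("potential", "current") %in% names(df)))
    stopf("trace file must have `potential` and `current` columns")
  class(df) <- c("cv_trace", "data.frame")
  df
}
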
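# layer-resolving cell widths for one layer (top -> bottom)
layer_cell_widths <- function(lay, z_refine = 1L) {
  n <- lay$n_cells
  r <- lay$grading
  w <- if (r == 1) rep(lay$thickness / n, n) else {
    raw <- r^(0:(n - 1))
    lay$thickness * raw / sum(raw)
  }
  if (z_refine > 1L) w <- rep(w / z_refine, each = z_refine)
  w
}

#' Build the voxelized foot-insole computational domain
#'
#' Discretizes a vertical layer stack over a rectangular footprint into a
#' structured, cell-centered grid. The z axis measures depth from the top
#' (deep muscle) face downward to the floor; grid planes are placed exactly
#' on every layer interface, so each material's z extent reproduces the
#' configured thicknesses to machine precision, and every layer spans at
#' least three cells.
#'
#' @param layers list of [layer()] objects, top (deep tissue) first; see
#'   [foot_insole_layers()].
#' @param footprint numeric length-2, slab length and width in m. The slab
#'   footprint replaces the anatomical foot outline: the layer stack and the
#'   lesion depth, not the outline, drive the vertical heat transfer.
#' @param dx,dy lateral cell size in m (default 2 mm).
#' @param z_refine integer >= 1; splits every vertical cell into `z_refine`
#'   equal parts (used for grid-convergence studies).
#' @return An object of class `domain_grid` with fields `x_edges`, `y_edges`,
#'   `z_edges` (m), `mat` (integer material id per cell, `nx x ny x nz`),
#'   `materials` (named list of [material_props()]), `layer_id` (layer index
#'   per z cell), `skin_depth` (depth of the plantar skin surface, m),
#'   `sock_face` (z face index of the skin-insole interface or `NA`).
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.05, 0.04), dx = 0.01)
#' dim(g$mat)
#' @export
build_domain <- function(layers, footprint = c(0.26, 0.09),
                         dx = 0.002, dy = dx, z_refine = 1L) {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec")))
    stopf("`layers` must be a non-empty list of layer_spec objects")
  if (length(footprint) != 2L || any(!is.finite(footprint)) || any(footprint <= 0))
    stopf("`footprint` must be two positive lengths (m)")
  check_number(dx, "dx", lower = 0, strict_lower = TRUE)
  check_number(dy, "dy", lower = 0, strict_lower = TRUE)
  z_refine <- as.integer(z_refine)
  if (z_refine < 1L) stopf("`z_refine` must be >= 1")
  if (footprint[1] < 2 * dx || footprint[2] < 2 * dy)
    stopf("footprint must be at least 2 lateral cells in each direction")

  nx <- max(2L, as.integer(round(footprint[1] / dx)))
  ny <- max(2L, as.integer(round(footprint[2] / dy)))
  x_edges <- seq(0, footprint[1], length.out = nx + 1L)
  y_edges <- seq(0, footprint[2], length.out = ny + 1L)

  widths <- lapply(layers, layer_cell_widths, z_refine = z_refine)
  nz_per <- lengths(widths)
  layer_id <- rep(seq_along(layers), nz_per)
  dz <- unlist(widths, use.names = FALSE)
  # place grid lines exactly on interfaces: cumulative sums per layer
  tops <- cumsum(c(0, vapply(layers, `[[`, 0, "thickness")))
  z_edges <- numeric(length(dz) + 1L)
  pos <- 1L
  for (i in seq_along(layers)) {
    w <- widths[[i]]
    z_edges[pos:(pos + length(w))] <- tops[i] + c(0, cumsum(w))
    z_edges[pos + length(w)] <- tops[i + 1]  # exact interface
    pos <- pos + length(w)
  }
  nz <- length(dz)

  # unique material table (by name + parameter values)
  mats <- list(); mat_of_layer <- integer(length(layers))
  for (i in seq_along(layers)) {
    m <- layers[[i]]$material
    hit <- 0L
    for (j in seq_along(mats)) if (identical(mats[[j]], m)) { hit <- j; break }
    if (!hit) { mats[[length(mats) + 1L]] <- m; hit <- length(mats) }
    mat_of_layer[i] <- hit
  }
  names(mats) <- vapply(mats, `[[`, "", "name")
  mat <- array(rep(mat_of_layer[layer_id], each = nx * ny), dim = c(nx, ny, nz))

  tissue_flags <- vapply(layers, `[[`, TRUE, "tissue")
  if (any(tissue_flags) && any(!tissue_flags)) {
    if (any(diff(tissue_flags) > 0))
      stopf("tissue layers must form one contiguous block above the insole")
    n_tissue_layers <- sum(tissue_flags)
    skin_depth <- tops[n_tissue_layers + 1L]
    sock_face <- sum(nz_per[seq_len(n_tissue_layers)])  # z face index
  } else {
    skin_depth <- if (any(tissue_flags)) tops[length(tops)] else NA_real_
    sock_face <- NA_integer_
  }

  structure(list(
    x_edges = x_edges, y_edges = y_edges, z_edges = z_edges,
    nx = nx, ny = ny, nz = nz,
    mat = mat, materials = mats, layers = layers, layer_id = layer_id,
    footprint = c(length = footprint[1], width = footprint[2]),
    skin_depth = skin_depth, sock_face = sock_face,
    lesion = NULL), class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("<domain_grid> %d x %d x %d cells (%.0f x %.0f mm footprint, %.2f mm deep)\n",
              x$nx, x$ny, x$nz, 1e3 * x$footprint[1], 1e3 * x$footprint[2],
              1e3 * max(x$z_edges)))
  cat(sprintf("  layers (top to bottom): %s\n",
              paste(vapply(x$layers, function(l)
                sprintf("%s[%.3gmm]", l$material$name, 1e3 * l$thickness), ""),
                collapse = " | ")))
  if (!is.null(x$lesion))
    cat(sprintf("  lesion: %s, centre depth %.1f mm, %d cells reassigned\n",
                x$lesion$type, 1e3 * x$lesion$center_depth, x$lesion$n_cells))
  invisible(x)
}

cell_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Specify a subcutaneous lesion inclusion
#'
#' The lesion is modelled as an oblate ellipsoid whose vertical semi-axis is
#' `height / 2` and whose equal lateral semi-axes solve
#' \eqn{V = \tfrac{4}{3}\pi a^2 c}: the published geometric constraints
#' (height and volume) are matched while the irregular outline, which is not
#' reproducible, is idealised. Depth is measured from the plantar skin
#' surface to the lesion centre.
#'
#' @param type `"inflammation"` (warms the tissue) or `"ischemia"` (cools it;
#'   arterial blood at 35 degC and strongly reduced conductivity/perfusion).
#' @param center_depth depth of the lesion centre below the skin surface, m.
#' @param center lateral `(x, y)` centre in m; defaults (NULL) to the S4
#'   sensor position of [default_sensor_layout()] for the grid footprint.
#' @param height full lesion height in m (default 2.5 mm).
#' @param volume lesion volume in m3 (default 1.5 cm3).
#' @param material optional [material_props()] override; defaults to the
#'   matching entry of [tissue_materials()].
#' @return An object of class `lesion_spec`.
#' @examples
#' lesion_spec("inflammation", center_depth = 2.6e-3, center = c(0.18, 0.06))
#' @export
lesion_spec <- function(type = c("inflammation", "ischemia"), center_depth,
                        center = NULL, height = 2.5e-3, volume = 1.5e-6,
                        material = NULL) {
  type <- match.arg(type)
  check_number(center_depth, "center_depth", lower = 0, strict_lower = TRUE)
  check_number(height, "height", lower = 0, strict_lower = TRUE)
  check_number(volume, "volume", lower = 0)
  c_semi <- height / 2
  a_semi <- if (volume > 0) sqrt(volume / (4 / 3 * pi * c_semi)) else 0
  if (volume > 0 && a_semi < c_semi)
    stopf("volume %.3g m3 is inconsistent with height %.3g m (lateral semi-axis < height/2)",
          volume, height)
  if (is.null(material)) material <- tissue_materials()[[type]]
  if (!inherits(material, "material_props"))
    stopf("`material` must be a material_props object")
  if (!is.null(center) && (length(center) != 2L || any(!is.finite(center))))
    stopf("`center` must be NULL or numeric length 2 (m)")
  structure(list(type = type, center_depth = center_depth, center = center,
                 height = height, volume = volume,
                 a_semi = a_semi, c_semi = c_semi, material = material),
            class = "lesion_spec")
}

#' Embed a lesion inclusion into a domain grid
#'
#' Reassigns every cell whose centre lies inside the lesion ellipsoid (and
#' inside the tissue sub-domain: the vertical extent is clipped at the skin
#' surface) to the lesion material. All other cells are untouched and the
#' grid itself is never re-meshed, so paired lesion/healthy solves share an
#' identical discretization.
#'
#' @param grid a [build_domain()] grid.
#' @param lesion a [lesion_spec()].
#' @return The modified `domain_grid`; `grid$lesion` records the type, centre
#'   depth, number of reassigned cells and their voxelized volume.
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.06, 0.06), dx = 0.004)
#' g2 <- embed_lesion(g, lesion_spec("inflammation", 2.6e-3, center = c(0.03, 0.03)))
#' g2$lesion$n_cells > 0
#' @export
embed_lesion <- function(grid, lesion) {
  if (!inherits(grid, "domain_grid")) stopf("`grid` must be a domain_grid")
  if (!inherits(lesion, "lesion_spec")) stopf("`lesion` must be a lesion_spec")
  if (lesion$volume == 0) return(grid)  # empty inclusion: no-op
  if (is.na(grid$skin_depth)) stopf("grid has no tissue sub-domain")
  center <- lesion$center
  if (is.null(center))
    stopf("lesion `center` must be set (lateral position in m)")
  if (center[1] < 0 || center[1] > grid$footprint[1] ||
      center[2] < 0 || center[2] > grid$footprint[2])
    stopf("lesion centre (%.3g, %.3g) lies outside the footprint", center[1], center[2])

  xc <- cell_centers(grid$x_edges); yc <- cell_centers(grid$y_edges)
  zc <- cell_centers(grid$z_edges)
  z0 <- grid$skin_depth - lesion$center_depth
  rx <- (xc - center[1]) / lesion$a_semi
  ry <- (yc - center[2]) / lesion$a_semi
  rz <- (zc - z0) / lesion$c_semi
  inside <- outer(outer(rx^2, ry^2, `+`), rz^2, `+`) <= 1
  # clip to the tissue sub-domain
  tissue_k <- zc < grid$skin_depth &
    vapply(grid$layer_id, function(i) grid$layers[[i]]$tissue, TRUE)
  inside[, , !tissue_k] <- FALSE

  mats <- grid$materials
  hit <- 0L
  for (j in seq_along(mats)) if (identical(mats[[j]], lesion$material)) { hit <- j; break }
  if (!hit) {
    mats[[length(mats) + 1L]] <- lesion$material
    names(mats)[length(mats)] <- lesion$material$name
    hit <- length(mats)
  }
  grid$materials <- mats
  grid$mat[inside] <- hit

  dxv <- diff(grid$x_edges); dyv <- diff(grid$y_edges); dzv <- diff(grid$z_edges)
  vol <- sum(outer(outer(dxv, dyv), dzv)[inside])
  grid$lesion <- list(type = lesion$type, center_depth = lesion$center_depth,
                      center = center, spec = lesion,
                      n_cells = sum(inside), voxel_volume = vol,
                      material_id = hit)
  grid
}
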
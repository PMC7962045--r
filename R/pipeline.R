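#' Configuration for the lesion depth sweep
#'
#' Bundles everything [run_depth_sweep()] needs. The defaults are the study
#' conditions of the published numerical experiment: six lesion centre
#' depths (1.6, 2.6, 3.4, 5.9, 8.4, 9.7 mm below the plantar skin surface),
#' two lesion types, sock present and absent, lesion laterally centred on
#' sensor S4, and a 0.1 degC detection threshold.
#'
#' @param depths lesion centre depths in m.
#' @param types character subset of `c("inflammation", "ischemia")`.
#' @param sock logical vector of sock settings to run.
#' @param layers layer stack (top first), see [foot_insole_layers()].
#' @param footprint,dx,z_refine grid parameters, see [build_domain()].
#' @param blood a [blood_props()].
#' @param floor_h,floor_T_env floor convection parameters.
#' @param sock_resistance contact resistance when the sock is worn, m2K/W.
#' @param layout a [default_sensor_layout()]; built from the footprint if NULL.
#' @param lesion_center lateral lesion centre (m); defaults to S4's position.
#' @param lesion_height,lesion_volume lesion geometry (m, m3).
#' @param threshold detection threshold, degC.
#' @return A `sweep_config` list.
#' @examples
#' cfg <- sweep_config(depths = c(1.6e-3, 2.6e-3), sock = TRUE, dx = 0.01)
#' @export
sweep_config <- function(depths = c(1.6, 2.6, 3.4, 5.9, 8.4, 9.7) * 1e-3,
                         types = c("inflammation", "ischemia"),
                         sock = c(TRUE, FALSE),
                         layers = foot_insole_layers(),
                         footprint = c(0.26, 0.09), dx = 0.002, z_refine = 1L,
                         blood = blood_props(),
                         floor_h = 5, floor_T_env = 20, sock_resistance = 0.02,
                         layout = NULL, lesion_center = NULL,
                         lesion_height = 2.5e-3, lesion_volume = 1.5e-6,
                         threshold = 0.1) {
  types <- match.arg(types, several.ok = TRUE)
  if (!length(depths) || any(depths <= 0)) stopf("`depths` must be positive (m)")
  if (!is.logical(sock) || !length(sock)) stopf("`sock` must be logical")
  if (is.null(layout))
    layout <- default_sensor_layout(foot_length = footprint[1],
                                    foot_width = footprint[2],
                                    threshold = threshold)
  if (is.null(lesion_center)) {
    s4 <- layout[layout$sensor == "S4", ]
    if (!nrow(s4)) stopf("layout has no sensor S4; supply `lesion_center`")
    lesion_center <- c(s4$x[1], s4$y[1])
  }
  structure(list(depths = depths, types = types, sock = unique(sock),
                 layers = layers, footprint = footprint, dx = dx,
                 z_refine = as.integer(z_refine), blood = blood,
                 floor_h = floor_h, floor_T_env = floor_T_env,
                 sock_resistance = sock_resistance,
                 layout = layout, lesion_center = lesion_center,
                 lesion_height = lesion_height, lesion_volume = lesion_volume,
                 threshold = threshold),
            class = "sweep_config")
}

sweep_bc <- function(config, sock_on) {
  boundary_spec(floor_h = config$floor_h, floor_T_env = config$floor_T_env,
                sock_resistance = if (sock_on) config$sock_resistance else 0)
}

#' Run the full lesion detectability experiment
#'
#' For every sock setting, solves the healthy baseline once and then each
#' lesion type at each depth on the *same* grid (the lesion is embedded by
#' cell reassignment, never by re-meshing), computes per-sensor temperature
#' deviations against the matching-sock baseline, flags detectability, and
#' summarises the deepest detectable depth per lesion type and sock setting.
#' The thermal pipeline contains no randomness: identical configurations
#' give identical reports. The sparse Cholesky symbolic factorization is
#' reused across all cases.
#'
#' @param config a [sweep_config()].
#' @param verbose print per-case progress.
#' @return A `detection_report`: `cases` (one row per lesion case with
#'   per-sensor deltas `S1..S8`, detectable flags `det_S1..det_S8`, the
#'   max-principle audit and solver residual), `baselines` (per-sock sensor
#'   temperatures), `summary` (deepest detectable depth per type and sock),
#'   `fingerprint`, and the `config`.
#' @examples
#' cfg <- sweep_config(depths = 2.6e-3, types = "inflammation", sock = TRUE,
#'                     footprint = c(0.26, 0.09), dx = 0.02)
#' rep <- run_depth_sweep(cfg)
#' rep$summary
#' @export
run_depth_sweep <- function(config, verbose = FALSE) {
  if (!inherits(config, "sweep_config")) stopf("`config` must be a sweep_config")
  grid <- build_domain(config$layers, footprint = config$footprint,
                       dx = config$dx, z_refine = config$z_refine)
  layout <- config$layout
  say <- function(...) if (verbose) message(sprintf(...))

  cases <- list(); baselines <- list(); factor <- NULL
  for (sock_on in config$sock) {
    bc <- sweep_bc(config, sock_on)
    say("baseline (sock = %s)", sock_on)
    base <- tryCatch(
      solve_steady(grid, config$blood, bc, factor = factor, keep_factor = TRUE),
      error = function(e) stopf("baseline solve (sock=%s) failed: %s",
                                sock_on, conditionMessage(e)))
    if (is.null(factor)) factor <- attr(base, "factor")
    attr(base, "factor") <- NULL
    bt <- read_sensors(base, layout)
    baselines[[length(baselines) + 1L]] <-
      cbind(data.frame(sock = sock_on), stats::setNames(as.list(bt$T), bt$sensor))
    for (type in config$types) {
      for (depth in config$depths) {
        case_id <- sprintf("%s_%.1fmm_%s", type, depth * 1e3,
                           if (sock_on) "sock" else "nosock")
        lg <- embed_lesion(grid, lesion_spec(
          type, center_depth = depth, center = config$lesion_center,
          height = config$lesion_height, volume = config$lesion_volume))
        say("case %s (%d lesion cells)", case_id, lg$lesion$n_cells)
        fld <- tryCatch(
          solve_steady(lg, config$blood, bc, factor = factor),
          error = function(e) stopf("case %s failed: %s", case_id,
                                    conditionMessage(e)))
        sd <- sensor_deltas(fld, base, layout, threshold = config$threshold)
        row <- data.frame(case_id = case_id, type = type,
                          depth_mm = depth * 1e3, sock = sock_on,
                          lesion_cells = lg$lesion$n_cells)
        row[sd$sensor] <- sd$delta
        row[paste0("det_", sd$sensor)] <- sd$detectable
        row$max_principle_ok <- as.logical(check_max_principle(fld))
        row$residual <- fld$residual
        cases[[length(cases) + 1L]] <- row
      }
    }
  }
  cases <- do.call(rbind, cases)
  baselines <- do.call(rbind, baselines)

  det_cols <- paste0("det_", layout$sensor)
  summ <- do.call(rbind, lapply(split(cases, list(cases$type, cases$sock), drop = TRUE),
    function(d) {
      hit <- apply(d[det_cols], 1, any)
      data.frame(type = d$type[1], sock = d$sock[1],
                 deepest_detectable_mm = if (any(hit)) max(d$depth_mm[hit]) else NA_real_)
    }))
  rownames(summ) <- NULL

  structure(list(cases = cases, baselines = baselines, summary = summ,
                 fingerprint = config_fingerprint(unclass(config)),
                 config = config),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %d lesion cases + %d baselines (fingerprint %s)\n",
              nrow(x$cases), nrow(x$baselines), substr(x$fingerprint, 1, 8)))
  cat("Deepest detectable lesion depth (mm):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot per-sensor deviations against lesion depth
#'
#' One line per sensor, one panel per sock setting, for a given lesion type,
#' with the +-threshold band marked.
#'
#' @param x a `detection_report`.
#' @param y unused.
#' @param type lesion type to plot.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.detection_report <- function(x, y, type = x$config$types[1], ...) {
  sensors <- x$config$layout$sensor
  socks <- sort(unique(x$cases$sock), decreasing = TRUE)
  op <- par(mfrow = c(1, length(socks)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (s in socks) {
    d <- x$cases[x$cases$type == type & x$cases$sock == s, ]
    d <- d[order(d$depth_mm), ]
    matplot(d$depth_mm, as.matrix(d[sensors]), type = "b", pch = 1:8, lty = 1,
            xlab = "lesion centre depth (mm)", ylab = "delta T at sensor (degC)",
            main = sprintf("%s, sock %s", type, if (s) "on" else "off"), ...)
    abline(h = c(-1, 1) * x$config$threshold, col = "grey50", lty = 2)
    legend("topright", legend = sensors, pch = 1:8, col = 1:6, cex = 0.6, bty = "n")
  }
  invisible(x)
}

#' Per-material temperature summary of a field
#'
#' Volume-weighted mean and range of temperature per material region,
#' together with cell counts - the numerical counterpart of reading regional
#' temperatures off a simulated thermal map.
#'
#' @param field a [solve_steady()] result.
#' @return data.frame with `material`, `n_cells`, `mean_T`, `min_T`, `max_T`.
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
#' summarize_field(solve_steady(g))
#' @export
summarize_field <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  g <- field$grid
  dxv <- diff(g$x_edges); dyv <- diff(g$y_edges); dzv <- diff(g$z_edges)
  V <- outer(outer(dxv, dyv), dzv)
  id <- as.vector(g$mat); tv <- as.vector(field$T); vv <- as.vector(V)
  out <- do.call(rbind, lapply(sort(unique(id)), function(m) {
    sel <- id == m
    data.frame(material = names(g$materials)[m], n_cells = sum(sel),
               mean_T = sum(tv[sel] * vv[sel]) / sum(vv[sel]),
               min_T = min(tv[sel]), max_T = max(tv[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Area-averaged temperature of a horizontal surface
#'
#' @param field a [solve_steady()] result.
#' @param surface `"insole_top"` (top cell layer of the first non-tissue
#'   layer), `"skin"` (bottom tissue cell layer) or `"floor"` (bottom cell
#'   layer of the domain).
#' @return Mean temperature in degC over the surface cells.
#' @examples
#' g <- build_domain(foot_insole_layers(), footprint = c(0.02, 0.02), dx = 0.01)
#' surface_mean_temperature(solve_steady(g), "insole_top")
#' @export
surface_mean_temperature <- function(field,
                                     surface = c("insole_top", "skin", "floor")) {
  stopifnot(inherits(field, "temperature_field"))
  surface <- match.arg(surface)
  g <- field$grid
  tissue_k <- vapply(g$layer_id, function(i) g$layers[[i]]$tissue, TRUE)
  k <- switch(surface,
    insole_top = if (any(!tissue_k)) which(!tissue_k)[1L]
                 else stopf("grid has no insole layers"),
    skin = if (any(tissue_k)) max(which(tissue_k))
           else stopf("grid has no tissue layers"),
    floor = g$nz)
  mean(field$T[, , k])
}
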
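#' Geometry of the transwell (CIM-plate) well
#'
#' One-dimensional reduction of the cylindrical well: the x axis runs from
#' the upper lid (`x_top`) down to the lower lid (`x_bottom`), with the
#' permeable membrane at `x_M`. All flux conditions use the downward normal.
#' The mesh is coarse (`dx_coarse`) away from the membrane and refined to
#' `dx_fine` inside `[x_M - fine_halfwidth, x_M + fine_halfwidth]`, where
#' the interface conditions require extra resolution to keep the solution
#' nonnegative.
#'
#' @param x_top coordinate of the upper lid, cm.
#' @param x_bottom coordinate of the lower lid, cm.
#' @param x_M membrane coordinate, cm.
#' @param dx_coarse coarse mesh step, cm.
#' @param dx_fine fine mesh step near the membrane, cm.
#' @param fine_halfwidth half-width of the refined zone, cm; defaults to one
#'   coarse step.
#' @return An object of class `assay_geometry`.
#' @export
assay_geometry <- function(x_top = 0, x_bottom = 1.8, x_M = 0.9,
                           dx_coarse = 1e-2, dx_fine = 1e-6,
                           fine_halfwidth = dx_coarse) {
  g <- list(x_top = as.numeric(x_top), x_bottom = as.numeric(x_bottom),
            x_M = as.numeric(x_M), dx_coarse = as.numeric(dx_coarse),
            dx_fine = as.numeric(dx_fine),
            fine_halfwidth = as.numeric(fine_halfwidth))
  if (!(g$x_top < g$x_M && g$x_M < g$x_bottom)) {
    stop("assay_geometry: need x_top < x_M < x_bottom", call. = FALSE)
  }
  if (!(g$dx_fine > 0 && g$dx_fine <= g$dx_coarse)) {
    stop("assay_geometry: need 0 < dx_fine <= dx_coarse", call. = FALSE)
  }
  if (g$fine_halfwidth <= 0 ||
      g$x_M - g$fine_halfwidth <= g$x_top ||
      g$x_M + g$fine_halfwidth >= g$x_bottom) {
    stop("assay_geometry: refined zone must lie strictly inside the well",
         call. = FALSE)
  }
  class(g) <- "assay_geometry"
  g
}

#' Initial conditions of the assay
#'
#' At seeding, cells occupy an interval `omega_u` of the upper chamber at
#' uniform density `u0`, and the serum fills the whole lower chamber at
#' density `phi0`. The seeded interval defaults to the slab of length
#' `n_total / u0` adjacent to the membrane from above (cells sediment onto
#' the membrane; the axis points downward).
#'
#' @param u0 initial cell density inside `omega_u`, cell/cm.
#' @param phi0 initial serum density in the lower chamber, ul/cm (0 for a
#'   basal, serum-free assay).
#' @param n_total seeded cell count, cells.
#' @param omega_u optional length-2 numeric, the seeded interval in cm; if
#'   `NULL` it is resolved against the geometry when the fields are built.
#' @return An object of class `initial_conditions`.
#' @export
initial_conditions <- function(u0, phi0, n_total, omega_u = NULL) {
  ic <- list(u0 = as.numeric(u0), phi0 = as.numeric(phi0),
             n_total = as.numeric(n_total), omega_u = omega_u)
  if (ic$u0 < 0 || ic$phi0 < 0 || ic$n_total < 0) {
    stop("initial_conditions: u0, phi0 and n_total must be nonnegative",
         call. = FALSE)
  }
  if (!is.null(omega_u)) {
    omega_u <- as.numeric(omega_u)
    if (length(omega_u) != 2 || omega_u[1] >= omega_u[2]) {
      stop("initial_conditions: omega_u must be an increasing length-2 interval",
           call. = FALSE)
    }
    if (ic$u0 > 0 &&
        abs(ic$u0 * diff(omega_u) - ic$n_total) > 1e-3 * ic$n_total) {
      stop("initial_conditions: u0 * |omega_u| must equal n_total within 0.1%",
           call. = FALSE)
    }
    ic$omega_u <- omega_u
  }
  class(ic) <- "initial_conditions"
  ic
}

#' Initial-condition presets per cell line and seeding
#'
#' The assays seeded 2e4, 3e4 or 4e4 cells per well; the corresponding
#' initial 1D densities are about 30200, 45300 and 60400 cell/cm (the same
#' 1.51 cell/cm-per-cell conversion for every line). The serum load of the
#' chemotactic assay is 18.39 ul/cm in the lower chamber; a basal assay has
#' none.
#'
#' @param cells seeded cell count (2e4 by default).
#' @param mode `"migration"` (serum in the lower chamber) or `"basal"`.
#' @return An [initial_conditions()] object.
#' @export
preset_initial_conditions <- function(cells = 2e4,
                                      mode = c("migration", "basal")) {
  mode <- match.arg(mode)
  initial_conditions(u0 = 1.51 * cells,
                     phi0 = if (mode == "migration") 18.39 else 0,
                     n_total = cells)
}

#' Time-marching settings
#'
#' @param dt time step, h (default 1e-3, the largest value keeping the
#'   scheme stable and nonnegative at the default mesh).
#' @param t_end final time, h; the assay observation window is 12 h.
#' @param mode `"migration"` or `"basal"`; basal runs zero out chemotaxis
#'   and growth ([make_basal_parameters()]) and start serum-free.
#' @param output_interval sampling step for recorded observables, h.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(dt = 1e-3, t_end = 12,
                                mode = c("migration", "basal"),
                                output_interval = 0.25) {
  mode <- match.arg(mode)
  s <- list(dt = as.numeric(dt), t_end = as.numeric(t_end), mode = mode,
            output_interval = as.numeric(output_interval))
  if (s$dt <= 0 || s$t_end <= 0) {
    stop("simulation_settings: dt and t_end must be positive", call. = FALSE)
  }
  if (s$output_interval < s$dt) {
    stop("simulation_settings: output_interval must be >= dt", call. = FALSE)
  }
  class(s) <- "simulation_settings"
  s
}
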
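#' Build the non-uniform finite-difference mesh
#'
#' Nodes are placed top to bottom: coarse spacing `dx_coarse` outside the
#' refined zone, fine spacing `dx_fine` inside it, and the membrane node is
#' duplicated into an upper trace and a lower trace sharing the coordinate
#' `x_M`. The two traces carry the one-sided limits of the fields on the
#' membrane, across which the solution is discontinuous.
#'
#' If the refined zone's edges do not coincide with coarse nodes they are
#' snapped to the nearest ones with a warning; if `dx_fine` does not divide
#' the half-zone exactly it is rounded to the nearest divisor.
#'
#' @param geometry an [assay_geometry()] object.
#' @return An object of class `assay_mesh`: node coordinates `x` (length
#'   `n`), 1-based index `m` of the upper membrane trace (the lower trace is
#'   `m + 1`), and the chamber index ranges.
#' @export
build_mesh <- function(geometry) {
  stopifnot(inherits(geometry, "assay_geometry"))
  g <- geometry
  n_above <- round((g$x_M - g$fine_halfwidth - g$x_top) / g$dx_coarse)
  n_below <- round((g$x_bottom - g$x_M - g$fine_halfwidth) / g$dx_coarse)
  zone_lo <- g$x_top + n_above * g$dx_coarse
  zone_hi <- g$x_bottom - n_below * g$dx_coarse
  if (abs(zone_lo - (g$x_M - g$fine_halfwidth)) > 1e-9 * g$dx_coarse ||
      abs(zone_hi - (g$x_M + g$fine_halfwidth)) > 1e-9 * g$dx_coarse) {
    warning("build_mesh: refined zone snapped to the nearest coarse nodes [",
            signif(zone_lo, 8), ", ", signif(zone_hi, 8), "]")
  }
  n_fine_up <- max(1L, round((g$x_M - zone_lo) / g$dx_fine))
  n_fine_lo <- max(1L, round((zone_hi - g$x_M) / g$dx_fine))
  h_up <- (g$x_M - zone_lo) / n_fine_up
  h_lo <- (zone_hi - g$x_M) / n_fine_lo

  x_above <- g$x_top + g$dx_coarse * (0:n_above)                     # 0..zone_lo
  x_fine_up <- zone_lo + h_up * seq_len(n_fine_up)                   # ..x_M
  x_fine_lo <- g$x_M + h_lo * seq_len(n_fine_lo)                     # ..zone_hi
  x_below <- zone_hi + g$dx_coarse * seq_len(n_below)                # ..x_bottom
  x <- c(x_above, x_fine_up, g$x_M, x_fine_lo, x_below)
  m <- n_above + 1L + n_fine_up  # index of the upper trace (1-based)
  x[m] <- g$x_M             # exact duplication
  n <- length(x)
  if (m < 3L || n - (m + 1L) < 3L) {
    stop("build_mesh: need at least three nodes on each side of the membrane ",
         "for the one-sided interface stencils", call. = FALSE)
  }
  mesh <- list(x = x, n = n, m = m,
               idx_upper = seq_len(m), idx_lower = (m + 1L):n,
               h_up = h_up, h_lo = h_lo, geometry = g)
  class(mesh) <- "assay_mesh"
  mesh
}

#' @export
print.assay_mesh <- function(x, ...) {
  cat(sprintf(paste0("Transwell mesh: %d stored nodes (%d geometric + ",
                     "duplicated membrane trace)\n"), x$n, x$n - 1L))
  cat(sprintf("  membrane at x = %g cm (traces at indices %d, %d)\n",
              x$geometry$x_M, x$m, x$m + 1L))
  cat(sprintf("  local spacings at the membrane: %g / %g cm\n", x$h_up, x$h_lo))
  invisible(x)
}

#' Composite trapezoid integral over one chamber
#'
#' The two chambers are integrated separately: the interval between the two
#' membrane traces has zero width, so the traces contribute only through
#' their own chamber. Used for cell counts and serum mass.
#'
#' @param f nodal values on the full mesh.
#' @param mesh an [assay_mesh()] object.
#' @param chamber `"upper"`, `"lower"` or `"both"`.
#' @return The integral (cells or ul).
#' @export
chamber_integral <- function(f, mesh, chamber = c("both", "upper", "lower")) {
  chamber <- match.arg(chamber)
  tr <- function(idx) {
    xs <- mesh$x[idx]
    fs <- f[idx]
    sum(diff(xs) * (fs[-length(fs)] + fs[-1]) / 2)
  }
  switch(chamber,
         upper = tr(mesh$idx_upper),
         lower = tr(mesh$idx_lower),
         both = tr(mesh$idx_upper) + tr(mesh$idx_lower))
}

#' Build the initial fields on a mesh
#'
#' Cells fill `omega_u` (by default the slab of length `n_total/u0` sitting
#' on the membrane from above) at density `u0`; serum fills the lower
#' chamber, lower trace included, at `phi0`. Everything else is zero.
#'
#' @param mesh an [assay_mesh()] object.
#' @param ic an [initial_conditions()] object.
#' @return A `field_state`: list with nodal vectors `u`, `phi` and time `t`.
#' @export
initialize_fields <- function(mesh, ic) {
  stopifnot(inherits(mesh, "assay_mesh"), inherits(ic, "initial_conditions"))
  g <- mesh$geometry
  omega <- ic$omega_u
  if (is.null(omega)) {
    if (ic$u0 > 0) {
      len <- ic$n_total / ic$u0
      if (len > g$x_M - g$x_top) {
        stop("initialize_fields: seeded slab does not fit the upper chamber",
             call. = FALSE)
      }
      omega <- c(g$x_M - len, g$x_M)
    } else {
      omega <- c(g$x_M, g$x_M)
    }
  }
  if (omega[1] < g$x_top - 1e-12 || omega[2] > g$x_M + 1e-12) {
    stop("initialize_fields: omega_u must lie inside the upper chamber",
         call. = FALSE)
  }
  u <- numeric(mesh$n)
  tol <- 1e-12
  sel <- mesh$idx_upper[mesh$x[mesh$idx_upper] >= omega[1] - tol &
                          mesh$x[mesh$idx_upper] <= omega[2] + tol]
  u[sel] <- ic$u0
  phi <- numeric(mesh$n)
  phi[mesh$idx_lower] <- ic$phi0
  state <- list(u = u, phi = phi, t = 0)
  class(state) <- "field_state"
  state
}
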
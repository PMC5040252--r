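# R-level surface of the finite-difference solver. The kernels live in
# src/fd_solver.cpp; these wrappers validate inputs, carry the field-state
# bookkeeping and assemble the flat parameter vector the kernels consume.

par_vector <- function(params, mesh) {
  validate_model_parameters(params)
  c(unlist(params), x_M = mesh$geometry$x_M)
}

check_state <- function(state, mesh) {
  stopifnot(inherits(state, "field_state"))
  if (length(state$u) != mesh$n || length(state$phi) != mesh$n) {
    stop("field state does not match the mesh (", mesh$n, " nodes)",
         call. = FALSE)
  }
  invisible(state)
}

#' Advective velocity field
#'
#' Per-node advective velocity `V = chi(phi) * dphi/dx + V_transp`: centred
#' gradient at interior nodes (with the local spacing on the non-uniform
#' mesh), one-sided at the lids, and the Kedem-Katchalsky flux relation
#' `dphi/dx = k_phi (phi_B - phi_T) / D_phi` at the two membrane traces.
#'
#' @param state a `field_state` (see [initialize_fields()]).
#' @param params a [model_parameters()] object.
#' @param mesh an [assay_mesh()] object.
#' @return Numeric vector of velocities, cm/h, one per stored node.
#' @export
advective_velocity <- function(state, params, mesh) {
  check_state(state, mesh)
  x <- mesh$x
  n <- mesh$n
  m <- mesh$m
  phi <- state$phi
  chi <- chemotactic_sensitivity(pmax(phi, 0), params)
  grad <- numeric(n)
  grad[1] <- (phi[2] - phi[1]) / (x[2] - x[1])
  grad[n] <- (phi[n] - phi[n - 1]) / (x[n] - x[n - 1])
  i <- setdiff(2:(n - 1), c(m, m + 1L))
  grad[i] <- (phi[i + 1] - phi[i - 1]) / (x[i + 1] - x[i - 1])
  grad[c(m, m + 1L)] <- params$k_phi * (phi[m + 1] - phi[m]) / params$D_phi
  chi * grad + params$V_transp
}

#' Advance the serum field by one time step
#'
#' Implicit central-in-space diffusion with the binding sink `-delta u phi`
#' explicit, outer zero-gradient rows and membrane transmission rows
#' assembled into the same banded solve. The cell field enters at the old
#' time level only.
#'
#' @inheritParams advective_velocity
#' @param dt time step, h.
#' @param negativity_tol relative negativity beyond which the step aborts
#'   as a stability violation; values above `-negativity_tol * max(field)`
#'   are tolerated as boundary-stencil round-off (see the methods
#'   vignette).
#' @return The state with `phi` replaced by its value at `t + dt` (time
#'   bookkeeping is left to the caller).
#' @export
advance_phi <- function(state, params, mesh, dt, negativity_tol = 1e-7) {
  check_state(state, mesh)
  stopifnot(dt > 0, negativity_tol >= 0)
  state$phi <- cpp_step_phi(mesh$x, mesh$m, state$u, state$phi,
                            par_vector(params, mesh), dt, negativity_tol)
  state
}

#' Advance the cell-density field by one time step
#'
#' Implicit central diffusion; explicit centred advection at the
#' chemotactic-plus-transport velocity with a `|V|`-weighted
#' artificial-viscosity second difference for stability; explicit
#' adhesion/spreading reaction; membrane rows enforcing the same
#' density-limited transmission flux on both traces. Serum is read at the
#' old time level. Aborts (rather than clipping) if negativity beyond
#' round-off appears, advising a smaller `dt`.
#'
#' @inheritParams advance_phi
#' @return The state with `u` replaced by its value at `t + dt`.
#' @export
advance_u <- function(state, params, mesh, dt, negativity_tol = 1e-7) {
  check_state(state, mesh)
  stopifnot(dt > 0, negativity_tol >= 0)
  state$u <- cpp_step_u(mesh$x, mesh$m, state$u, state$phi,
                        par_vector(params, mesh), dt, negativity_tol)
  state
}

#' Simulate the transwell migration assay
#'
#' Marches the coupled cell/serum system from seeding to `t_end`,
#' alternating the serum and cell updates (both reading the previous level's
#' cross-couplings), and records the lower-chamber cell number, the total
#' cell number and the total serum at `output_interval` cadence. In basal
#' mode the parameters pass through [make_basal_parameters()] and the run
#' starts serum-free.
#'
#' @param params a [model_parameters()] object.
#' @param geometry an [assay_geometry()] object.
#' @param ic an [initial_conditions()] object.
#' @param settings a [simulation_settings()] object.
#' @param snapshots if `TRUE`, store the full fields at every sample time.
#' @param negativity_tol relative negativity tolerance of the
#'   non-negativity guard (default 1e-7); see [advance_u()].
#' @return An object of class `assay_simulation` with elements `times` (h),
#'   `n_lower` (cells in the lower chamber), `n_total` (cells), `fbs_total`
#'   (ul), final fields, and optionally snapshot matrices (samples x nodes).
#' @export
simulate_assay <- function(params, geometry = assay_geometry(),
                           ic = preset_initial_conditions(),
                           settings = simulation_settings(),
                           snapshots = FALSE, negativity_tol = 1e-7) {
  stopifnot(inherits(settings, "simulation_settings"))
  if (settings$mode == "basal") {
    params <- make_basal_parameters(params)
    ic$phi0 <- 0
  }
  mesh <- build_mesh(geometry)
  state <- initialize_fields(mesh, ic)
  nsteps <- max(1L, as.integer(round(settings$t_end / settings$dt)))
  sample_every <- max(1L, as.integer(round(settings$output_interval / settings$dt)))
  raw <- cpp_march(mesh$x, mesh$m, state$u, state$phi,
                   par_vector(params, mesh), settings$dt, nsteps,
                   sample_every, isTRUE(snapshots), negativity_tol)
  res <- list(times = raw$t, n_lower = raw$n_lower, n_total = raw$n_total,
              fbs_total = raw$fbs_total,
              final_state = structure(list(u = raw$u_final,
                                           phi = raw$phi_final,
                                           t = nsteps * settings$dt),
                                      class = "field_state"),
              mesh = mesh, params = params, ic = ic, settings = settings)
  if (isTRUE(snapshots)) {
    res$u_snapshots <- raw$u_snapshots
    res$phi_snapshots <- raw$phi_snapshots
  }
  class(res) <- "assay_simulation"
  res
}

#' @export
print.assay_simulation <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Transwell assay simulation (%s mode): t = 0..%g h, %d samples\n",
              x$settings$mode, x$times[n], n))
  cat(sprintf("  cells in lower chamber at %g h: %.1f of %.1f total\n",
              x$times[n], x$n_lower[n], x$n_total[n]))
  invisible(x)
}

#' Export a simulation's sampled observables as CSV
#'
#' Columns `time_h`, `n_lower_cells`, `n_total_cells`, `fbs_total`.
#'
#' @param result an `assay_simulation`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(result, path) {
  stopifnot(inherits(result, "assay_simulation"))
  df <- data.frame(time_h = result$times, n_lower_cells = result$n_lower,
                   n_total_cells = result$n_total,
                   fbs_total = result$fbs_total)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
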
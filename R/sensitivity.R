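#' Observed output of the sensitivity analysis
#'
#' The scalar model output used for the local sensitivity analysis: the
#' Cell Index at the final observation time (12 h), obtained from the
#' migrated-cell-number curve through the linear Cell-Index map. With a
#' proportional map the derived relative indices do not depend on the
#' slope.
#'
#' @param result an `assay_simulation` reaching `t_obs`.
#' @param map a [cell_index_map()]; proportional by default.
#' @param t_obs observation time, h (default 12).
#' @return Cell Index at `t_obs` (scalar).
#' @export
output_functional <- function(result, map = cell_index_map(), t_obs = 12) {
  stopifnot(inherits(result, "assay_simulation"))
  tmax <- max(result$times)
  if (tmax < t_obs - 1e-9) {
    stop("output_functional: simulation ends at ", tmax, " h, before t_obs = ",
         t_obs, " h", call. = FALSE)
  }
  nb <- stats::approx(result$times, result$n_lower, xout = t_obs)$y
  map$a * nb + map$b
}

#' Local sensitivity index of a perturbed output
#'
#' One-at-a-time indices for a parameter perturbed from `p0` by `eps`:
#' the sensitivity index is the magnitude of the ratio of relative
#' variations,
#' \deqn{S = \left|\frac{f(p_0\pm\varepsilon)-f(p_0)}{f(p_0)}\right|
#'   \left(\frac{\varepsilon}{p_0}\right)^{-1},}
#' and the signed percentage output variation is
#' \eqn{\Delta f_{rel} = 100\,(f(p_0\pm\varepsilon)-f(p_0))/f(p_0)}.
#' For a 5% perturbation the two are tied: `S = |delta_f_rel| / 5`.
#'
#' @param f0 baseline output, nonzero.
#' @param f_pert output at the perturbed parameter.
#' @param p0 baseline parameter value, nonzero.
#' @param eps absolute perturbation, positive.
#' @return List with `S` (magnitude) and `delta_f_rel` (signed, percent).
#' @export
sensitivity_index <- function(f0, f_pert, p0, eps) {
  if (f0 == 0) stop("sensitivity_index: baseline output is zero", call. = FALSE)
  if (p0 == 0 || eps <= 0) {
    stop("sensitivity_index: need p0 != 0 and eps > 0", call. = FALSE)
  }
  rel <- (f_pert - f0) / f0
  list(S = abs(rel) / (eps / p0), delta_f_rel = 100 * rel)
}

#' One-at-a-time local sensitivity table
#'
#' Perturbs each named parameter by `+/- eps_fraction` (5% by default), one
#' at a time, reruns the full migration simulation and tabulates the
#' percentage variation of the 12 h Cell Index and the sensitivity index
#' `S`. The baseline is simulated once. A proportional Cell-Index map is
#' used so the indices are independent of the (experiment-specific) slope.
#'
#' @param params baseline [model_parameters()].
#' @param geometry an [assay_geometry()].
#' @param ic an [initial_conditions()].
#' @param settings a [simulation_settings()] reaching `t_obs`.
#' @param param_names parameters to perturb; defaults to every calibrated
#'   constant of the model.
#' @param eps_fraction relative perturbation (default 0.05).
#' @param directions `"+"`, `"-"` or both.
#' @param t_obs observation time of the output functional, h.
#' @return A data frame of class `sensitivity_table`: one row per parameter
#'   and direction with columns `parameter`, `direction`, `p0`, `f0`,
#'   `f_pert`, `delta_f_rel_percent`, `S`.
#' @export
sensitivity_table <- function(params, geometry = assay_geometry(),
                              ic = preset_initial_conditions(),
                              settings = simulation_settings(),
                              param_names = c("D_u", "chi1", "chi2",
                                              "V_transp", "alpha2", "delta",
                                              "k_u1", "k_u2", "k_u3", "k_phi"),
                              eps_fraction = 0.05,
                              directions = c("+", "-"), t_obs = 12) {
  validate_model_parameters(params)
  if (eps_fraction <= 0) {
    stop("sensitivity_table: eps_fraction must be positive", call. = FALSE)
  }
  unknown <- setdiff(param_names, names(params))
  if (length(unknown) > 0) {
    stop("sensitivity_table: unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  directions <- match.arg(directions, c("+", "-"), several.ok = TRUE)
  base <- simulate_assay(params, geometry, ic, settings)
  f0 <- output_functional(base, t_obs = t_obs)
  rows <- list()
  for (nm in param_names) {
    p0 <- params[[nm]]
    if (p0 == 0) {
      stop("sensitivity_table: parameter ", nm,
           " is zero; a relative perturbation is undefined", call. = FALSE)
    }
    for (dir in directions) {
      eps <- eps_fraction * p0
      pert <- params
      pert[[nm]] <- p0 + if (dir == "+") eps else -eps
      res <- simulate_assay(pert, geometry, ic, settings)
      fp <- output_functional(res, t_obs = t_obs)
      idx <- sensitivity_index(f0, fp, p0, eps)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, direction = dir, p0 = p0, f0 = f0, f_pert = fp,
        delta_f_rel_percent = idx$delta_f_rel, S = idx$S)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "eps_fraction") <- eps_fraction
  class(out) <- c("sensitivity_table", "data.frame")
  out
}
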
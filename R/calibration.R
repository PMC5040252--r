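#' Fit a logistic trajectory to a proliferation curve
#'
#' Proliferation assays on the impedance plates show logistic growth of the
#' Cell Index. Fitting
#' \deqn{c(t) = K / (1 + (K/c_0 - 1)\, e^{-r t})}
#' yields the growth rate `r` and the plateau `K` in Cell-Index units.
#' Because the model's serum factor is normalised to 1 at the
#' proliferation-assay concentration `phi_bar`, the fitted rate is the
#' logistic coefficient `alpha1` directly. When the seeded cell number is
#' known, the proportional Cell-Index map `a = c_0 / n_seed` converts the
#' capacity to cell units.
#'
#' @param curve a [ci_curve()] spanning growth through plateau, values > 0.
#' @param n_seed seeded cell number behind `c_0` (optional).
#' @param weights optional per-point weights (e.g. `1/sd^2`); unweighted by
#'   default.
#' @return List with `alpha1` (1/h), `capacity_ci` (Cell Index), `c0`
#'   (Cell Index at t = 0), `map` (a [cell_index_map()], or `NULL` without
#'   `n_seed`), `capacity_cells` (if `n_seed` given) and `fitted` values.
#' @export
fit_logistic_proliferation <- function(curve, n_seed = NULL, weights = NULL) {
  stopifnot(inherits(curve, "ci_curve"))
  v <- curve$value
  t <- curve$time_h
  if (any(v <= 0)) {
    stop("fit_logistic_proliferation: curve values must be positive",
         call. = FALSE)
  }
  if (stats::sd(v) < 1e-12 * mean(v)) {
    # flat curve: zero growth, capacity = the constant level
    map <- if (!is.null(n_seed)) cell_index_map(mean(v) / n_seed) else NULL
    return(list(alpha1 = 0, capacity_ci = mean(v), c0 = mean(v), map = map,
                capacity_cells = if (!is.null(n_seed)) n_seed else NULL,
                fitted = rep(mean(v), length(v))))
  }
  K0 <- max(v) * 1.05
  c00 <- max(v[1], min(v))
  early <- seq_len(max(2L, min(5L, length(v))))
  r0 <- max(1e-3, stats::coef(stats::lm(log(v[early]) ~ t[early]))[[2]])
  fit_args <- list(
    value ~ K / (1 + (K / c0 - 1) * exp(-r * time_h)),
    data = data.frame(time_h = t, value = v),
    start = list(K = K0, c0 = c00, r = r0),
    lower = c(K = 1e-12, c0 = 1e-12, r = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) fit_args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, fit_args),
    error = function(e) {
      stop("fit_logistic_proliferation: logistic fit failed (",
           conditionMessage(e), "); the curve may be degenerate or ",
           "non-monotone", call. = FALSE)
    })
  cf <- stats::coef(fit)
  map <- if (!is.null(n_seed)) cell_index_map(cf[["c0"]] / n_seed) else NULL
  list(alpha1 = cf[["r"]], capacity_ci = cf[["K"]], c0 = cf[["c0"]],
       map = map,
       capacity_cells = if (!is.null(map)) cf[["K"]] / map$a else NULL,
       fitted = stats::fitted(fit))
}

#' Doubling time from the exponential-growth window
#'
#' Log-linear fit of the curve on a window inside the exponential phase;
#' the doubling time is `ln(2) / slope`.
#'
#' @param curve a [ci_curve()] with positive values on the window.
#' @param window length-2 time interval, h; defaults to the whole curve.
#' @return Doubling time, h.
#' @export
estimate_doubling_time <- function(curve, window = range(curve$time_h)) {
  stopifnot(inherits(curve, "ci_curve"))
  keep <- curve$time_h >= window[1] & curve$time_h <= window[2]
  if (sum(keep) < 2) {
    stop("estimate_doubling_time: window contains fewer than two points",
         call. = FALSE)
  }
  v <- curve$value[keep]
  if (any(v <= 0)) {
    stop("estimate_doubling_time: curve must be positive on the window",
         call. = FALSE)
  }
  slope <- stats::coef(stats::lm(log(v) ~ curve$time_h[keep]))[[2]]
  if (slope <= 0) {
    stop("estimate_doubling_time: nonpositive growth slope; ",
         "doubling time undefined", call. = FALSE)
  }
  log(2) / slope
}

#' Declare a staged calibration problem
#'
#' The calibration protocol is staged: growth parameters come from
#' proliferation curves; the parameters without chemotactic or growth
#' effects (`D_u`, `V_transp`, `k_u1`, `k_u2`, `k_u3`) are calibrated on
#' basal migration curves with `chi1 = alpha1 = 0`; the chemotactic and
#' serum parameters (`chi1`, `chi2`, `alpha2`, `delta`, `k_phi`) are then
#' calibrated on the chemotactic migration curves with everything else
#' frozen.
#'
#' @param stage `"proliferation"`, `"basal"` or `"migration"`.
#' @param free named list of length-2 positive bounds for the free
#'   parameters (ignored for the proliferation stage).
#' @param params fixed [model_parameters()] (also supplies the initial
#'   guess for the free parameters).
#' @param geometry,ic,settings forward-simulation inputs; `settings$mode`
#'   is forced to match the stage.
#' @param target the experimental/average [ci_curve()] to fit.
#' @param map optional [cell_index_map()]; if `NULL` the proportional slope
#'   is profiled out by least squares at every objective evaluation.
#' @param n_starts multi-start count for the simplex search (default 5).
#' @param max_eval objective-evaluation cap per start.
#' @param seed RNG seed for the Latin-hypercube starts.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(stage = c("basal", "migration", "proliferation"),
                                free = list(), params = preset_parameters("sarc"),
                                geometry = assay_geometry(),
                                ic = preset_initial_conditions(),
                                settings = simulation_settings(),
                                target = NULL, map = NULL,
                                n_starts = 5, max_eval = 400, seed = 1) {
  stage <- match.arg(stage)
  validate_model_parameters(params)
  if (length(free) > 0) {
    unknown <- setdiff(names(free), names(params))
    if (length(unknown) > 0) {
      stop("calibration_problem: unknown free parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ok <- vapply(free, function(b) length(b) == 2 && b[1] > 0 && b[1] < b[2],
                 logical(1))
    if (!all(ok)) {
      stop("calibration_problem: each bound must be a positive increasing pair",
           call. = FALSE)
    }
  }
  if (stage != "proliferation") {
    settings$mode <- if (stage == "basal") "basal" else "migration"
  }
  structure(list(stage = stage, free = free, params = params,
                 geometry = geometry, ic = ic, settings = settings,
                 target = target, map = map, n_starts = n_starts,
                 max_eval = max_eval, seed = seed),
            class = "calibration_problem")
}

# relative MSE of a simulation against the target, profiling the
# proportional Cell-Index slope when no map is fixed
calibration_objective <- function(problem) {
  target <- problem$target
  force(target)
  function(par_vec) {
    params <- problem$params
    for (nm in names(par_vec)) params[[nm]] <- par_vec[[nm]]
    res <- tryCatch(
      simulate_assay(params, problem$geometry, problem$ic, problem$settings),
      error = function(e) NULL)
    if (is.null(res)) return(Inf)
    nb <- migrated_cell_number(res)
    keep <- target$time_h >= min(nb$time_h) - 1e-12 &
      target$time_h <= max(nb$time_h) + 1e-12
    ce <- target$value[keep]
    cs <- stats::approx(nb$time_h, nb$value, xout = target$time_h[keep])$y
    if (!is.null(problem$map)) {
      cs <- problem$map$a * cs + problem$map$b
    } else {
      denom <- sum(cs^2)
      a <- if (denom > 0) sum(cs * ce) / denom else 0
      if (a <= 0) return(Inf)
      cs <- a * cs
    }
    sum((cs - ce)^2) / sum(ce^2)
  }
}

#' Calibrate model parameters against a target curve
#'
#' Minimises the relative MSE between the simulated and
#' target Cell-Index curves over the free parameters, by Nelder-Mead
#' simplex on log-parameters (all free parameters are positive) with
#' box-bound penalties and a fixed-seed Latin-hypercube multi-start. The
#' first start is the problem's own parameter values. For the
#' proliferation stage the logistic fit of
#' [fit_logistic_proliferation()] is used instead of the PDE forward model.
#'
#' After the search, near-flat directions (free parameters whose +/-20%
#' perturbation changes the objective by less than 1e-4) are reported
#' rather than silently returned.
#'
#' @param problem a [calibration_problem()].
#' @return An object of class `calibration_result`: estimated values,
#'   achieved objective, objective at the initial guess, per-start
#'   objectives, evaluation count, convergence codes and the flat-direction
#'   report.
#' @export
calibrate_parameters <- function(problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  if (problem$stage == "proliferation") {
    fit <- fit_logistic_proliferation(problem$target)
    out <- list(stage = "proliferation",
                par = c(alpha1 = fit$alpha1),
                extra = fit, objective = NA_real_, evaluations = NA_integer_)
    class(out) <- "calibration_result"
    return(out)
  }
  if (is.null(problem$target)) {
    stop("calibrate_parameters: the problem has no target curve", call. = FALSE)
  }
  n_eval <- 0L
  obj_raw <- calibration_objective(problem)
  free <- problem$free
  if (length(free) == 0) {
    val <- obj_raw(numeric(0))
    out <- list(stage = problem$stage, par = numeric(0), objective = val,
                initial_objective = val, evaluations = 1L,
                flat_directions = character(0), convergence = 0L)
    class(out) <- "calibration_result"
    return(out)
  }
  nms <- names(free)
  lo <- log(vapply(free, `[`, numeric(1), 1))
  hi <- log(vapply(free, `[`, numeric(1), 2))
  obj_log <- function(z) {
    n_eval <<- n_eval + 1L
    out_of_box <- pmax(z - hi, 0) + pmax(lo - z, 0)
    if (any(out_of_box > 0)) return(1e6 * (1 + sum(out_of_box^2)))
    p <- exp(z)
    names(p) <- nms
    obj_raw(p)
  }
  z0 <- log(pmin(pmax(vapply(nms, function(nm) problem$params[[nm]],
                             numeric(1)), exp(lo)), exp(hi)))
  initial_objective <- obj_log(z0)
  starts <- list(z0)
  if (problem$n_starts > 1) {
    set.seed(problem$seed)
    lh <- lhs::randomLHS(problem$n_starts - 1L, length(nms))
    for (i in seq_len(nrow(lh))) {
      starts[[i + 1L]] <- lo + lh[i, ] * (hi - lo)
    }
  }
  best <- NULL
  start_objectives <- numeric(length(starts))
  convergence <- integer(length(starts))
  for (i in seq_along(starts)) {
    fit <- if (length(nms) == 1L) {
      # simplex is unreliable in one dimension; golden-section search instead
      stats::optim(starts[[i]], obj_log, method = "Brent",
                   lower = lo, upper = hi,
                   control = list(maxit = problem$max_eval))
    } else {
      stats::optim(starts[[i]], obj_log, method = "Nelder-Mead",
                   control = list(maxit = problem$max_eval, reltol = 1e-10))
    }
    start_objectives[i] <- fit$value
    convergence[i] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value) || best$value >= 1e6) {
    stop("calibrate_parameters: objective non-finite at every start; trace: ",
         paste(signif(start_objectives, 4), collapse = ", "), call. = FALSE)
  }
  par <- exp(best$par)
  names(par) <- nms
  # identifiability guard: report directions the objective barely sees
  flat <- character(0)
  for (nm in nms) {
    up <- par; up[[nm]] <- min(par[[nm]] * 1.2, exp(hi[[nm]]))
    dn <- par; dn[[nm]] <- max(par[[nm]] * 0.8, exp(lo[[nm]]))
    d_up <- abs(obj_raw(up) - best$value)
    d_dn <- abs(obj_raw(dn) - best$value)
    if (max(d_up, d_dn) < 1e-4) flat <- c(flat, nm)
  }
  out <- list(stage = problem$stage, par = par, objective = best$value,
              initial_objective = initial_objective,
              start_objectives = start_objectives,
              evaluations = n_eval, convergence = convergence,
              flat_directions = flat)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result (stage: ", x$stage, ")\n", sep = "")
  if (length(x$par) > 0) {
    for (nm in names(x$par)) cat(sprintf("  %-10s %g\n", nm, x$par[[nm]]))
  }
  if (!is.na(x$objective)) {
    cat(sprintf("  relative MSE: %.4g (%d evaluations)\n",
                x$objective, x$evaluations))
  }
  if (length(x$flat_directions %||% character(0)) > 0) {
    cat("  near-flat directions: ",
        paste(x$flat_directions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
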
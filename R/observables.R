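#' Time-series curve container
#'
#' A light container for both simulated and experimental Cell-Index (or
#' cell-number) curves: a data frame with `time_h`, `value` and optional
#' `sd`, plus a label.
#'
#' @param time_h strictly increasing times, h.
#' @param value curve values (Cell Index or cells).
#' @param sd optional per-point standard deviation (nonnegative).
#' @param label short description.
#' @return A data frame of class `ci_curve`.
#' @export
ci_curve <- function(time_h, value, sd = NULL, label = "") {
  time_h <- as.numeric(time_h)
  value <- as.numeric(value)
  if (length(time_h) != length(value)) {
    stop("ci_curve: time_h and value must have equal length", call. = FALSE)
  }
  if (length(time_h) > 1 && any(diff(time_h) <= 0)) {
    stop("ci_curve: times must be strictly increasing", call. = FALSE)
  }
  df <- data.frame(time_h = time_h, value = value)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(value) || any(sd < 0)) {
      stop("ci_curve: sd must be nonnegative and match value", call. = FALSE)
    }
    df$sd <- sd
  }
  attr(df, "label") <- label
  class(df) <- c("ci_curve", "data.frame")
  df
}

#' Linear map from cell number to Cell Index
#'
#' The impedance readout depends linearly on the (lower-chamber) cell
#' number: `CI = a * N + b`. The slope/intercept can be estimated from a
#' proliferation experiment with a known seeded number; for relative
#' quantities (sensitivity indices, relative MSE of proportional curves) a
#' proportional map (`b = 0`) suffices and the slope cancels.
#'
#' @param slope Cell Index per cell, must be positive.
#' @param intercept Cell Index offset; 0 gives a proportional map.
#' @return An object of class `cell_index_map`.
#' @export
cell_index_map <- function(slope = 1, intercept = 0) {
  if (!is.numeric(slope) || slope <= 0) {
    stop("cell_index_map: slope must be positive", call. = FALSE)
  }
  structure(list(a = as.numeric(slope), b = as.numeric(intercept),
                 proportional = intercept == 0),
            class = "cell_index_map")
}

#' Number of migrated cells over time
#'
#' The cells counted by the sensor are those past the membrane: the cell
#' density integrated (composite trapezoid) over the entire lower chamber,
#' lower membrane trace included.
#'
#' @param result an `assay_simulation` from [simulate_assay()].
#' @return A [ci_curve()] in cells.
#' @export
migrated_cell_number <- function(result) {
  stopifnot(inherits(result, "assay_simulation"))
  ci_curve(result$times, result$n_lower, label = "migrated cells")
}

#' Convert a cell-number curve to Cell Index
#'
#' @param n_curve a [ci_curve()] in cells.
#' @param map a [cell_index_map()].
#' @return A [ci_curve()] in Cell Index units.
#' @export
to_cell_index <- function(n_curve, map) {
  stopifnot(inherits(n_curve, "ci_curve"), inherits(map, "cell_index_map"))
  out <- n_curve
  out$value <- map$a * n_curve$value + map$b
  if (!is.null(out$sd)) out$sd <- map$a * out$sd
  attr(out, "label") <- paste0(attr(n_curve, "label"), " (Cell Index)")
  out
}

#' Relative mean-squared error between two curves
#'
#' The goodness-of-fit functional used throughout:
#' \deqn{\mathrm{MSE} = \sum_i (\hat c_i - c_i)^2 / \sum_i c_i^2,}
#' where the simulated curve is linearly interpolated onto the experimental
#' time grid. Experimental points outside the simulated time range are
#' dropped rather than extrapolated. The value is invariant under joint
#' rescaling of both curves.
#'
#' @param sim simulated [ci_curve()].
#' @param exp experimental [ci_curve()] (the reference grid).
#' @return Dimensionless relative MSE (>= 0).
#' @export
relative_mse <- function(sim, exp) {
  stopifnot(inherits(sim, "ci_curve"), inherits(exp, "ci_curve"))
  keep <- exp$time_h >= min(sim$time_h) - 1e-12 &
    exp$time_h <= max(sim$time_h) + 1e-12
  if (!any(keep)) {
    stop("relative_mse: curves have disjoint time ranges", call. = FALSE)
  }
  ce <- exp$value[keep]
  if (sum(ce^2) == 0) {
    stop("relative_mse: experimental curve is identically zero on the overlap",
         call. = FALSE)
  }
  cs <- stats::approx(sim$time_h, sim$value, xout = exp$time_h[keep])$y
  sum((cs - ce)^2) / sum(ce^2)
}
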
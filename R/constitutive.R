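#' Saturating chemotactic sensitivity
#'
#' The chemotactic response of the cells to the serum gradient saturates at
#' high chemoattractant concentration:
#' \deqn{\chi(\varphi) = \chi_1 \varphi / (\chi_2 + \varphi).}
#' It is zero at `phi = 0`, equals `chi1/2` at the half-saturation point
#' `phi = chi2`, increases monotonically and is bounded by `chi1`.
#'
#' @param phi chemoattractant concentration(s), ul/cm; must be nonnegative.
#' @param params a [model_parameters()] object.
#' @return Chemotactic sensitivity, cm^3/(ul h); vectorised over `phi`.
#' @export
chemotactic_sensitivity <- function(phi, params) {
  validate_model_parameters(params)
  if (any(!is.finite(phi)) || any(phi < 0)) {
    stop("chemotactic_sensitivity: phi must be finite and nonnegative",
         call. = FALSE)
  }
  params$chi1 * phi / (params$chi2 + phi)
}

#' Spatial weight of the adhesion/spreading term
#'
#' The impedance sensor sits on the lower face of the membrane, so the
#' adhesion/spreading contribution is spatially confined to the membrane
#' neighbourhood and the whole lower chamber. With `xbar = x_M -
#' x_bar_offset` (a couple of cell diameters above the membrane):
#' \deqn{W(x) = 0 \ (x \le \bar x);\quad
#'   \exp\!\left(-\frac{(\bar x - x_M)^2}{(\bar x - x_M)^2-(x - x_M)^2}+1\right)
#'   \ (\bar x < x \le x_M);\quad 1 \ (x > x_M).}
#' The bump factor rises continuously from 0 at `xbar` to 1 at the membrane.
#'
#' @param x position(s) in the well, cm (axis oriented top to bottom).
#' @param geometry an [assay_geometry()] object.
#' @param params a [model_parameters()] object (uses `x_bar_offset`).
#' @return Dimensionless weight in `[0, 1]`, vectorised over `x`.
#' @export
spreading_weight <- function(x, geometry, params) {
  if (params$x_bar_offset <= 0) {
    stop("spreading_weight: x_bar_offset must be positive", call. = FALSE)
  }
  x_M <- geometry$x_M
  xbar <- x_M - params$x_bar_offset
  d2 <- (xbar - x_M)^2
  w <- numeric(length(x))
  mid <- x > xbar & x <= x_M
  w[mid] <- exp(-d2 / (d2 - (x[mid] - x_M)^2) + 1)
  w[x > x_M] <- 1
  w
}

#' Adhesion/spreading (logistic growth) rate of the cell density
#'
#' Serum-promoted increase of the sensed cell signal (adhesion, spreading
#' and, on longer horizons, proliferation), logistic in the cell density and
#' saturating in serum. The serum factor is normalised so that it equals 1
#' at the proliferation-assay concentration `phi_bar`, which is where the
#' logistic rate `alpha1` was estimated:
#' \deqn{g(u,\varphi) = \alpha_1 u (1 - u/\alpha_3)
#'   \frac{\varphi}{\alpha_2+\varphi}
#'   \frac{\alpha_2+\bar\varphi}{\bar\varphi} W(x).}
#'
#' @param u cell density, cell/cm.
#' @param phi serum concentration, ul/cm.
#' @param x position, cm.
#' @param params a [model_parameters()] object.
#' @param geometry an [assay_geometry()] object.
#' @return Rate of change of `u`, cell/(cm h); vectorised.
#' @export
adhesion_spreading_rate <- function(u, phi, x, params, geometry) {
  if (params$alpha1 > 0 && params$phi_bar <= 0) {
    stop("adhesion_spreading_rate: phi_bar must be positive when alpha1 > 0",
         call. = FALSE)
  }
  if (any(u < 0) || any(phi < 0)) {
    stop("adhesion_spreading_rate: u and phi must be nonnegative", call. = FALSE)
  }
  if (params$alpha1 == 0) return(numeric(length(u)) * u)
  fbs <- phi / (params$alpha2 + phi) * (params$alpha2 + params$phi_bar) / params$phi_bar
  params$alpha1 * u * (1 - u / params$alpha3) * fbs *
    spreading_weight(x, geometry, params)
}

#' Density-limited membrane transmission coefficient for cells
#'
#' Kedem-Katchalsky transmission through the porous membrane, reduced by
#' crowding on both faces: by the cell density on the upper face (`u_T`)
#' and by the total cell number already in the lower chamber raised to
#' `p_crowd`:
#' \deqn{k_u(u) = \frac{k_{u1}}{1 + k_{u2} u_T + k_{u3} N_B^p}.}
#' It equals `k_u1` for an empty membrane and decreases strictly in both
#' arguments.
#'
#' @param u_T cell density on the upper membrane face, cell/cm.
#' @param n_lower cell number integrated over the lower chamber, cells.
#' @param params a [model_parameters()] object.
#' @return Transmission coefficient, cm/h.
#' @export
membrane_transmission <- function(u_T, n_lower, params) {
  if (any(u_T < 0) || any(n_lower < 0)) {
    stop("membrane_transmission: u_T and n_lower must be nonnegative",
         call. = FALSE)
  }
  params$k_u1 / (1 + params$k_u2 * u_T + params$k_u3 * n_lower^params$p_crowd)
}
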
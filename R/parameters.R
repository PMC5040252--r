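#' Constitutive parameters of the transwell migration model
#'
#' Bundles every constant of the coupled cell-density / chemoattractant
#' system: diffusivities, the saturating chemotactic response, the
#' spontaneous (basal) transmembrane transport speed, the logistic
#' adhesion/spreading term, serum consumption, and the Kedem-Katchalsky
#' membrane transmission coefficients with their crowding corrections.
#'
#' Units follow the 1D (per-length) formulation of the model: densities are
#' cells per cm of well height, serum is microlitres per cm.
#'
#' @param D_u cell diffusion coefficient, cm^2/h.
#' @param D_phi chemoattractant (FBS) diffusion coefficient, cm^2/h.
#' @param chi1 first chemotactic constant (saturated chemotactic velocity
#'   response), cm^3/(ul h).
#' @param chi2 second chemotactic constant (half-saturation of the
#'   chemotactic response), ul/cm.
#' @param V_transp spontaneous transport speed through the membrane pores,
#'   cm/h, directed from the upper to the lower chamber (the x axis points
#'   downward).
#' @param alpha1 logistic adhesion/spreading (growth) coefficient, 1/h.
#' @param alpha2 serum half-saturation in the growth term, ul/cm.
#' @param alpha3 logistic carrying capacity, cell/cm.
#' @param phi_bar serum concentration of the proliferation experiment used to
#'   normalise the growth term, ul/cm.
#' @param delta serum binding/consumption rate, cm/(h cell).
#' @param k_u1 membrane transmission coefficient for cells, cm/h.
#' @param k_u2 upper-side crowding coefficient, cm/cell.
#' @param k_u3 lower-side crowding coefficient, 1/cell^2 (acts on the
#'   lower-chamber cell number raised to `p_crowd`).
#' @param k_phi membrane transmission coefficient for serum, cm/h.
#' @param p_crowd exponent of the lower-chamber crowding contribution,
#'   dimensionless; defaults to 2.
#' @param x_bar_offset distance above the membrane at which the spreading
#'   weight vanishes, cm; default 4e-3 cm, about two 20 um cell diameters.
#'
#' @return An object of class `model_parameters` (a validated named list).
#' @seealso [preset_parameters()] for the three built-in cell-line sets,
#'   [make_basal_parameters()] for the basal-migration reduction.
#' @export
model_parameters <- function(D_u, D_phi, chi1, chi2, V_transp,
                             alpha1, alpha2, alpha3, phi_bar, delta,
                             k_u1, k_u2, k_u3, k_phi,
                             p_crowd = 2, x_bar_offset = 4e-3) {
  p <- list(D_u = D_u, D_phi = D_phi, chi1 = chi1, chi2 = chi2,
            V_transp = V_transp, alpha1 = alpha1, alpha2 = alpha2,
            alpha3 = alpha3, phi_bar = phi_bar, delta = delta,
            k_u1 = k_u1, k_u2 = k_u2, k_u3 = k_u3, k_phi = k_phi,
            p_crowd = p_crowd, x_bar_offset = x_bar_offset)
  p <- lapply(p, as.numeric)
  class(p) <- "model_parameters"
  validate_model_parameters(p)
  p
}

validate_model_parameters <- function(p) {
  stopifnot(inherits(p, "model_parameters"))
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("model_parameters: all fields must be finite scalars; offending: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (any(unlist(p) < 0)) {
    stop("model_parameters: all coefficients must be nonnegative; offending: ",
         paste(names(p)[unlist(p) < 0], collapse = ", "), call. = FALSE)
  }
  if (p$alpha3 <= 0) stop("model_parameters: alpha3 must be positive", call. = FALSE)
  if (p$chi2 <= 0) stop("model_parameters: chi2 must be positive", call. = FALSE)
  if (p$alpha1 > 0 && p$phi_bar <= 0) {
    stop("model_parameters: phi_bar must be positive when alpha1 > 0 ",
         "(the growth term is normalised at phi = phi_bar)", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Transwell migration model parameters\n")
  u <- c(D_u = "cm^2/h", D_phi = "cm^2/h", chi1 = "cm^3/(ul h)",
         chi2 = "ul/cm", V_transp = "cm/h", alpha1 = "1/h",
         alpha2 = "ul/cm", alpha3 = "cell/cm", phi_bar = "ul/cm",
         delta = "cm/(h cell)", k_u1 = "cm/h", k_u2 = "cm/cell",
         k_u3 = "cell^-2", k_phi = "cm/h", p_crowd = "-", x_bar_offset = "cm")
  for (nm in names(x)) {
    cat(sprintf("  %-13s %-12g %s\n", nm, x[[nm]], u[[nm]]))
  }
  invisible(x)
}

#' Built-in cell-line parameter presets
#'
#' Returns the calibrated parameter set for one of the three tumour cell
#' lines characterised with the real-time transwell assay: chondrosarcoma
#' (`"sarc"`), fibrosarcoma (`"ht1080"`) or melanoma (`"a375"`). Values were
#' obtained from proliferation assays (growth parameters), basal-migration
#' curves (diffusion, transport, membrane transmission) and chemotactic
#' migration curves (chemotaxis, serum consumption and transmission), at
#' 2e4 seeded cells per well.
#'
#' @param line one of `"sarc"`, `"ht1080"`, `"a375"` (case-insensitive).
#' @return A [model_parameters()] object.
#' @export
preset_parameters <- function(line = c("sarc", "ht1080", "a375")) {
  line <- match.arg(tolower(line), c("sarc", "ht1080", "a375"))
  shared <- list(D_phi = 3.7e-3, chi2 = 4.75e-8, alpha2 = 1e-6,
                 phi_bar = 19.64, k_u1 = 2, k_u3 = 6e-8, k_phi = 8.8e-2)
  own <- switch(line,
    sarc   = list(D_u = 1e-3,   chi1 = 3e-3,   V_transp = 9e-3,
                  alpha1 = 0.154, alpha3 = 2.08e5, delta = 1e-8,
                  k_u2 = 1e-5),
    ht1080 = list(D_u = 2.5e-3, chi1 = 2.5e-3, V_transp = 2e-3,
                  alpha1 = 0.135, alpha3 = 2.26e5, delta = 1e-8,
                  k_u2 = 5e-5),
    a375   = list(D_u = 8e-4,   chi1 = 1e-3,   V_transp = 1.3e-9,
                  alpha1 = 0.118, alpha3 = 1.04e5, delta = 3.5e-5,
                  k_u2 = 2e-8))
  do.call(model_parameters, c(own, shared))
}

#' Reduce a parameter set to the basal-migration submodel
#'
#' In the basal assay no chemoattractant gradient is present, so chemotaxis
#' and serum-driven adhesion/spreading are switched off: `chi1 = alpha1 = 0`.
#' With these values the cell-density equation decouples from the serum
#' equation and only the cell dynamics need to be simulated. All other
#' fields are returned unchanged; the operation is idempotent.
#'
#' @param params a [model_parameters()] object.
#' @return The same object with `chi1` and `alpha1` set to zero.
#' @export
make_basal_parameters <- function(params) {
  validate_model_parameters(params)
  params$chi1 <- 0
  params$alpha1 <- 0
  params
}

#' Read or write parameter sets as structured config files
#'
#' Parameter sets are serialised as a flat named block keyed by the field
#' names of [model_parameters()]. The format is chosen from the file
#' extension: `.json` or `.yaml`/`.yml`.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_parameters()` returns a [model_parameters()] object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("read_parameters: unsupported extension '", ext, "'", call. = FALSE))
  if (!is.null(raw$parameters)) raw <- raw$parameters
  known <- names(formals(model_parameters))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("read_parameters: ignoring unknown fields: ",
            paste(extra, collapse = ", "))
  }
  do.call(model_parameters, raw[intersect(names(raw), known)])
}

#' @rdname read_parameters
#' @param params a [model_parameters()] object to serialise.
#' @export
write_parameters <- function(params, path) {
  validate_model_parameters(params)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("write_parameters: unsupported extension '", ext, "'", call. = FALSE))
  invisible(path)
}
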
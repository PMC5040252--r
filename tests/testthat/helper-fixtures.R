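# Shared fixtures: cheap geometries and settings used across the suite.
# Migration-mode runs need a refined membrane zone (the interface rows are
# ill-conditioned at coarse spacing there); dx_fine = 1e-4 keeps runs fast
# while preserving the scheme's behaviour.

fast_geometry <- function(dx = 0.01, dxf = 1e-4) {
  assay_geometry(dx_coarse = dx, dx_fine = dxf)
}

fast_basal_settings <- function(dt = 1e-2, t_end = 12) {
  simulation_settings(dt = dt, t_end = t_end, mode = "basal")
}

fast_migration_settings <- function(dt = 2e-3, t_end = 12) {
  simulation_settings(dt = dt, t_end = t_end, mode = "migration")
}

sarc <- preset_parameters("sarc")

# exact logistic Cell-Index trajectory
logistic_curve <- function(times, K, c0, r) {
  ci_curve(times, K / (1 + (K / c0 - 1) * exp(-r * times)), label = "logistic")
}

make_rtca_table <- function(time_h, ci_mean, ci_sd = NULL, label = "toy") {
  df <- data.frame(time_h = time_h, ci_mean = ci_mean)
  if (!is.null(ci_sd)) df$ci_sd <- ci_sd
  structure(list(label = label, data = df, has_sd = !is.null(ci_sd)),
            class = "rtca_table")
}
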
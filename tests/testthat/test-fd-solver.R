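test_that("mesh construction counts nodes and duplicates the membrane", {
  # uniform spacing: 181 geometric nodes + 1 duplicated trace
  mesh <- build_mesh(assay_geometry(dx_coarse = 0.01, dx_fine = 0.01))
  expect_equal(mesh$n, 182L)
  expect_equal(mesh$x[mesh$m], 0.9)
  expect_equal(mesh$x[mesh$m + 1L], 0.9)
  expect_true(all(diff(mesh$x[-mesh$m]) > 0))
  expect_equal(mesh$x[1], 0)
  expect_equal(mesh$x[mesh$n], 1.8)
  # default refined mesh: 89 + 20000 + 89 intervals -> 20179 + 1 nodes
  mesh_f <- build_mesh(assay_geometry())
  expect_equal(mesh_f$n, 20180L)
  expect_equal(sum(diff(mesh_f$x)), 1.8)
  # misaligned refined zone is snapped with a warning
  expect_warning(build_mesh(assay_geometry(dx_coarse = 0.07, dx_fine = 1e-3)),
                 "snapped")
})

test_that("initial fields place the slab on the membrane and serum below", {
  mesh <- build_mesh(fast_geometry())
  ic <- preset_initial_conditions(2e4)
  st <- initialize_fields(mesh, ic)
  expect_equal(chamber_integral(st$u, mesh, "both"), ic$n_total,
               tolerance = 2e-2)
  expect_true(all(st$u[mesh$x > 0.9] == 0))
  expect_true(all(st$u[mesh$x < 0.9 - ic$n_total / ic$u0 - 0.011] == 0))
  expect_equal(st$u[mesh$m], ic$u0)
  expect_true(all(st$phi[mesh$idx_upper] == 0))
  expect_true(all(st$phi[mesh$idx_lower] == ic$phi0))
  expect_equal(chamber_integral(st$phi, mesh, "lower"), 0.9 * ic$phi0)
})

test_that("advective velocity combines the serum gradient and transport", {
  mesh <- build_mesh(build_geom <- fast_geometry())
  p <- sarc
  st <- initialize_fields(mesh, preset_initial_conditions(2e4))
  # uniform serum: only spontaneous transport remains
  st0 <- st
  st0$phi <- rep(5, mesh$n)
  expect_equal(advective_velocity(st0, p, mesh),
               rep(p$V_transp, mesh$n))
  # chi1 = 0 kills the chemotactic part whatever the gradient
  p0 <- p
  p0$chi1 <- 0
  expect_equal(advective_velocity(st, p0, mesh), rep(p$V_transp, mesh$n))
  # linear serum with slope s at the half-saturation level: V = chi1 s/2 + Vt
  s <- 2.5
  i <- 20L  # uniform-spacing interior node
  stl <- st
  stl$phi <- p$chi2 + s * (mesh$x - mesh$x[i])
  expect_equal(advective_velocity(stl, p, mesh)[i],
               p$chi1 * s / 2 + p$V_transp, tolerance = 1e-10)
})

test_that("serum step: uniform fields reduce to the explicit binding decay", {
  mesh <- build_mesh(fast_geometry())
  p <- sarc
  st <- structure(list(u = rep(1e4, mesh$n), phi = rep(10, mesh$n), t = 0),
                  class = "field_state")
  dt <- 1e-3
  # delta = 0: nothing moves
  p0 <- p
  p0$delta <- 0
  expect_equal(advance_phi(st, p0, mesh, dt)$phi, st$phi, tolerance = 1e-12)
  # uniform reaction-only update phi * (1 - delta u dt) at every node
  pd <- p
  pd$delta <- 1e-6
  out <- advance_phi(st, pd, mesh, dt)$phi
  expect_equal(out, rep(10 * (1 - 1e-6 * 1e4 * dt), mesh$n),
               tolerance = 1e-10)
})

test_that("serum mass is conserved without binding and decays with it", {
  g <- fast_geometry()
  mesh <- build_mesh(g)
  ic <- preset_initial_conditions(2e4)
  p0 <- sarc
  p0$delta <- 0
  r0 <- simulate_assay(p0, g, ic, fast_migration_settings())
  drift <- abs(r0$fbs_total[length(r0$fbs_total)] / r0$fbs_total[1] - 1)
  expect_lt(drift, 1e-9)
  rd <- simulate_assay(sarc, g, ic, fast_migration_settings())
  expect_true(all(diff(rd$fbs_total) <= 1e-12 * rd$fbs_total[1]))
})

test_that("cell step: uniform state with no forcing is a fixed point", {
  mesh <- build_mesh(fast_geometry())
  p <- make_basal_parameters(sarc)
  p$V_transp <- 0
  st <- structure(list(u = rep(2e4, mesh$n), phi = numeric(mesh$n), t = 0),
                  class = "field_state")
  out <- advance_u(st, p, mesh, 1e-3)$u
  expect_equal(out, st$u, tolerance = 1e-12)
})

test_that("per-step mass error is a decaying membrane transient", {
  # without growth the trapezoid cell count should be invariant; the
  # constraint rows (lids, traces) are not flux-balanced cells, so a small
  # per-step error remains: largest on the first step while the membrane
  # boundary layer forms, then decaying
  mesh <- build_mesh(assay_geometry())
  p <- make_basal_parameters(sarc)
  st <- initialize_fields(mesh, preset_initial_conditions(2e4, "basal"))
  m0 <- chamber_integral(st$u, mesh)
  errs <- numeric(5)
  for (k in 1:5) {
    st <- advance_u(st, p, mesh, 1e-3)
    m1 <- chamber_integral(st$u, mesh)
    errs[k] <- abs(m1 / m0 - 1)
    m0 <- m1
  }
  expect_lt(errs[1], 5e-5)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[5], 5e-7)
})

test_that("membrane flux is continuous across the traces at every step", {
  g <- fast_geometry()
  mesh <- build_mesh(g)
  p <- sarc
  st <- initialize_fields(mesh, preset_initial_conditions(2e4))
  m <- mesh$m
  x <- mesh$x
  dt <- 1e-3
  for (k in 1:30) {
    phi_new <- advance_phi(st, p, mesh, dt)$phi
    # coefficients frozen at the old level, as in the scheme
    NB <- chamber_integral(st$u, mesh, "lower")
    ku <- membrane_transmission(st$u[m], NB, p)
    dphidx <- p$k_phi * (st$phi[m + 1] - st$phi[m]) / p$D_phi
    chiT <- chemotactic_sensitivity(max(st$phi[m], 0), p)
    chiB <- chemotactic_sensitivity(max(st$phi[m + 1], 0), p)
    u <- advance_u(st, p, mesh, dt)$u
    flux_up <- p$D_u * (3 * u[m] - 4 * u[m - 1] + u[m - 2]) /
      (2 * (x[m] - x[m - 1])) -
      u[m] * (chiT * dphidx + p$V_transp)
    flux_lo <- p$D_u * (-3 * u[m + 1] + 4 * u[m + 2] - u[m + 3]) /
      (2 * (x[m + 2] - x[m + 1])) -
      u[m + 1] * (chiB * dphidx + p$V_transp)
    jump <- ku * (u[m + 1] - u[m])
    scale <- max(abs(c(flux_up, flux_lo, jump, 1)))
    expect_lt(abs(flux_up - jump) / scale, 1e-8)
    expect_lt(abs(flux_lo - jump) / scale, 1e-8)
    st$u <- u
    st$phi <- phi_new
  }
})

test_that("an empty well stays empty", {
  g <- fast_geometry()
  ic <- initial_conditions(u0 = 0, phi0 = 18.39, n_total = 0)
  r <- simulate_assay(sarc, g, ic, fast_migration_settings(dt = 1e-2))
  expect_true(all(r$n_lower == 0))
  expect_true(all(r$n_total == 0))
  expect_true(all(r$final_state$u == 0))
})

test_that("halving the time step barely changes the 12 h migrated count", {
  g <- fast_geometry()
  ic <- preset_initial_conditions(2e4)
  r1 <- simulate_assay(sarc, g, ic, fast_migration_settings(dt = 2e-3))
  r2 <- simulate_assay(sarc, g, ic, fast_migration_settings(dt = 1e-3))
  nb1 <- r1$n_lower[length(r1$n_lower)]
  nb2 <- r2$n_lower[length(r2$n_lower)]
  expect_lt(abs(nb1 / nb2 - 1), 0.01)
})

test_that("with no forcing the two chambers equilibrate to a flat profile", {
  g <- assay_geometry(x_top = 0, x_bottom = 0.2, x_M = 0.1,
                      dx_coarse = 5e-3, dx_fine = 1e-4)
  p <- make_basal_parameters(sarc)
  p$V_transp <- 0
  p$delta <- 0
  ic <- initial_conditions(u0 = 3e4, phi0 = 0, n_total = 1500)
  r <- simulate_assay(p, g, ic,
                      simulation_settings(dt = 0.05, t_end = 300,
                                          mode = "basal",
                                          output_interval = 10),
                      snapshots = TRUE)
  spread <- apply(r$u_snapshots, 1, function(u) max(u) - min(u))
  # monotone decay of the spread after the initial transient
  tail_spread <- spread[r$times > 50]
  expect_true(all(diff(tail_spread) <= 1e-8 * spread[1]))
  u_final <- r$u_snapshots[nrow(r$u_snapshots), ]
  expect_lt((max(u_final) - min(u_final)) / mean(u_final), 1e-6)
  # the flat level carries the discrete initial mass over the 0.2 cm well
  expect_equal(mean(u_final), r$n_total[1] / 0.2, tolerance = 1e-3)
})

test_that("the march agrees with an independent method-of-lines reference", {
  g <- assay_geometry(dx_coarse = 0.05, dx_fine = 1e-3)
  ic <- preset_initial_conditions(2e4, "basal")
  nb_mol <- mol_basal_nb12(sarc, g, ic)
  # the coarse lids extrapolate visibly negative here; the loosened guard
  # is intentional for this validation configuration
  r <- simulate_assay(sarc, g, ic, fast_basal_settings(dt = 1e-2),
                      negativity_tol = 1e-2)
  nb_fd <- r$n_lower[length(r$n_lower)]
  expect_lt(abs(nb_fd / nb_mol - 1), 0.02)
})

test_that("instability is reported as a negativity abort, not clipped", {
  # coarse membrane spacing in migration mode is the documented failure mode
  g <- assay_geometry(dx_coarse = 0.01, dx_fine = 0.01)
  expect_error(
    simulate_assay(sarc, g, preset_initial_conditions(2e4),
                   fast_migration_settings(dt = 1e-3)),
    "negative value")
})
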
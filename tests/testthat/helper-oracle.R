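# Independent method-of-lines reference for basal runs: the same spatial
# semi-discretisation (constraint rows eliminated algebraically) integrated
# in time by deSolve's lsoda instead of the package's IMEX march. Used only
# as a cross-check oracle; it shares no time-stepping code with the solver.

mol_basal_nb12 <- function(params, geometry, ic, t_end = 12) {
  p <- make_basal_parameters(params)
  mesh <- build_mesh(geometry)
  x <- mesh$x
  n <- mesh$n
  m <- mesh$m
  st <- initialize_fields(mesh, ic)
  int_idx <- setdiff(seq_len(n), c(1L, n, m, m + 1L))
  c0 <- p$D_u / (2 * (x[2] - x[1]))
  cN <- p$D_u / (2 * (x[n] - x[n - 1]))
  cT <- p$D_u / (2 * (x[m] - x[m - 1]))
  cB <- p$D_u / (2 * (x[m + 2] - x[m + 1]))
  Vt <- p$V_transp
  w_lower <- local({  # trapezoid weights of the lower chamber
    idx <- mesh$idx_lower
    w <- numeric(n)
    for (k in seq_along(idx)[-length(idx)]) {
      i <- idx[k]
      j <- idx[k + 1]
      w[i] <- w[i] + (x[j] - x[i]) / 2
      w[j] <- w[j] + (x[j] - x[i]) / 2
    }
    w
  })
  reconstruct <- function(ui) {
    u <- numeric(n)
    u[int_idx] <- ui
    u[1] <- (4 * c0 * u[2] - c0 * u[3]) / (3 * c0 + Vt)
    u[n] <- (4 * cN * u[n - 1] - cN * u[n - 2]) / (3 * cN - Vt)
    u[m] <- u[m - 1]
    u[m + 1] <- u[m + 2]
    for (it in 1:4) {  # k_u depends on the traces: fixed-point iteration
      NB <- sum(w_lower * u)
      ku <- membrane_transmission(max(u[m], 0), max(NB, 0), p)
      A <- matrix(c(3 * cT - Vt + ku, -ku,
                    ku, -3 * cB - Vt - ku), 2, 2, byrow = TRUE)
      b <- c(cT * (4 * u[m - 1] - u[m - 2]), -cB * (4 * u[m + 2] - u[m + 3]))
      tr <- solve(A, b)
      u[m] <- tr[1]
      u[m + 1] <- tr[2]
    }
    u
  }
  rhs <- function(t, ui, parms) {
    u <- reconstruct(ui)
    flux <- numeric(n - 1)
    for (i in seq_len(n - 1)) {
      if (i == m) next
      flux[i] <- Vt * 0.5 * (u[i] + u[i + 1]) -
        0.5 * abs(Vt) * (u[i + 1] - u[i])
    }
    du <- numeric(n)
    for (i in int_idx) {
      hm <- x[i] - x[i - 1]
      hp <- x[i + 1] - x[i]
      lap <- 2 / (hm + hp) * ((u[i + 1] - u[i]) / hp - (u[i] - u[i - 1]) / hm)
      du[i] <- p$D_u * lap -
        (flux[i] - flux[i - 1]) / (0.5 * (x[i + 1] - x[i - 1]))
    }
    list(du[int_idx])
  }
  sol <- deSolve::ode(y = st$u[int_idx], times = c(0, t_end), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-6)
  u_final <- reconstruct(sol[nrow(sol), -1])
  chamber_integral(u_final, mesh, "lower")
}
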
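# Shared fixtures: hand-built communities and an independent fixed-step
# RK4 integrator used as a reference oracle for the adaptive solver.

# Community with explicit matrices; Z = 0 gives a uniform conjugation-rate
# matrix equal to gamma_bar (or zero under a mask).
make_community <- function(A, s = 0.1, gamma_bar = 0, c_cost = 0.005,
                           focal = 1L, Z = NULL, mask = NULL) {
  N <- nrow(A)
  if (is.null(Z)) Z <- matrix(0, N, N)
  structure(list(
    A = A, s_vec = rep_len(s, N),
    r_vec = calibrate_growth_rates(A, s),
    Z = Z, gamma_bar = gamma_bar, gamma_noise_rel = 0.1,
    Gamma = conjugation_matrix(gamma_bar, Z, 0.1, mask),
    mask = mask, c = c_cost, focal = as.integer(focal),
    seed = NA_integer_, id = 1L
  ), class = "hgt_community")
}

single_taxon_community <- function(r = 0.1, s = 0.1, gamma = 0, c_cost = 0) {
  cm <- make_community(matrix(0, 1, 1), s = s, gamma_bar = gamma,
                       c_cost = c_cost)
  cm$r_vec <- r
  cm
}

# Closed-form logistic solution with carrying capacity K = r/s.
logistic_solution <- function(t, x0, r, s) {
  K <- r / s
  K * x0 * exp(r * t) / (K + x0 * (exp(r * t) - 1))
}

# Fixed-step classical RK4 on the same right-hand side, independent of
# deSolve. Returns the state at the end of the span.
rk4_integrate <- function(community, Xs, Xr, D, params, t_end, h = 1e-3) {
  f <- function(Xs, Xr) glv_hgt_rhs(Xs, Xr, D, community, params)
  n_steps <- round(t_end / h)
  stopifnot(abs(n_steps * h - t_end) < 1e-9)
  for (k in seq_len(n_steps)) {
    k1 <- f(Xs, Xr)
    k2 <- f(Xs + h / 2 * k1$dXs, Xr + h / 2 * k1$dXr)
    k3 <- f(Xs + h / 2 * k2$dXs, Xr + h / 2 * k2$dXr)
    k4 <- f(Xs + h * k3$dXs, Xr + h * k3$dXr)
    Xs <- Xs + h / 6 * (k1$dXs + 2 * k2$dXs + 2 * k3$dXs + k4$dXs)
    Xr <- Xr + h / 6 * (k1$dXr + 2 * k2$dXr + 2 * k3$dXr + k4$dXr)
  }
  list(Xs = Xs, Xr = Xr)
}
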
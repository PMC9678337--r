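test_that("calibrated equilibrium is an exact zero of the right-hand side", {
  set.seed(11)
  p <- hgt_params()
  comm <- hgtstab:::draw_community(p, 321)
  d <- glv_hgt_rhs(rep(1, 10), rep(0, 10), 0, comm, p)
  expect_true(all(abs(d$dXs) < 1e-14))
  expect_true(all(d$dXr == 0))
  # and the integrator holds the fixed point
  tr <- integrate_phase(comm, list(Xs = rep(1, 10), Xr = rep(0, 10)),
                        c(0, 500), 0, p)
  expect_true(max(abs(final_state(tr, p)$Xs - 1)) < 1e-6)
})

test_that("right-hand side matches hand-substituted values", {
  p <- hgt_params(N = 1, beta_s = 1)
  # X (r - s X) - beta_s D X = 1*(0.1 - 0.1) - 1*0.1*1 = -0.1
  cm <- single_taxon_community(r = 0.1, s = 0.1)
  d <- glv_hgt_rhs(1, 0, 0.1, cm, p)
  expect_equal(d$dXs, -0.1)
  # transfer term gamma Xs Xr appears with opposite signs in each compartment
  cm <- single_taxon_community(r = 0.1, s = 0.1, gamma = 1e-3, c_cost = 0)
  p0 <- hgt_params(N = 1, c_cost = 0)
  d <- glv_hgt_rhs(0.5, 0.5, 0, cm, p0)
  transfer <- 1e-3 * 0.5 * 0.5
  growth <- 0.5 * (0.1 - 0.1 * 1)
  expect_equal(d$dXs, growth - transfer)
  expect_equal(d$dXr, growth + transfer)
  expect_equal(d$dXs + d$dXr, 2 * growth)
  expect_error(glv_hgt_rhs(c(1, 1), 0, 0, cm, p0), "dimension")
})

test_that("conjugation conserves taxon totals when the gene is free", {
  set.seed(13)
  p <- hgt_params(c_cost = 0, delta = 0)
  comm <- hgtstab:::draw_community(p, 77)
  comm$c <- 0
  Xs <- runif(10, 0.2, 1); Xr <- runif(10, 0, 0.8)
  with_g <- glv_hgt_rhs(Xs, Xr, 0, comm, p)
  comm0 <- set_gamma_bar(comm, 0)
  no_g <- glv_hgt_rhs(Xs, Xr, 0, comm0, p)
  expect_equal(with_g$dXs + with_g$dXr, no_g$dXs + no_g$dXr, tolerance = 1e-12)
})

test_that("single-taxon growth matches the closed-form logistic solution", {
  p <- hgt_params(N = 1)
  cm <- single_taxon_community(r = 0.1, s = 0.1)
  times <- c(0, 10, 25, 50, 100, 200)
  tr <- integrate_phase(cm, list(Xs = 0.01, Xr = 0), times, 0, p)
  expect_equal(tr$Xs[, 1], logistic_solution(times, 0.01, 0.1, 0.1),
               tolerance = 1e-7)
  expect_lt(abs(tr$Xs[length(times), 1] - 1), 1e-4)  # carrying capacity r/s
})

test_that("gene-free compartments form an invariant subspace", {
  set.seed(17)
  p <- hgt_params(gamma_bar = 0, delta = 0)
  comm <- hgtstab:::draw_community(p, 404)
  st0 <- list(Xs = rep(0.1, 10), Xr = rep(0, 10))
  st0$Xr[comm$focal] <- 0.1; st0$Xs[comm$focal] <- 0
  tr <- integrate_phase(comm, st0, seq(0, 500, by = 100), 0, p)
  background <- setdiff(1:10, comm$focal)
  expect_true(all(tr$Xr[, background] == 0))
})

test_that("adaptive solver agrees with a fixed-step RK4 reference", {
  p <- hgt_params(N = 1)
  cm <- single_taxon_community(r = 0.1, s = 0.1, gamma = 1e-3, c_cost = 0.005)
  ref <- rk4_integrate(cm, 0.3, 0.2, 0.02, p, t_end = 40, h = 1e-3)
  tr <- integrate_phase(cm, list(Xs = 0.3, Xr = 0.2), c(0, 40), 0.02, p)
  st <- final_state(tr, p)
  expect_lt(abs(st$Xs - ref$Xs) / ref$Xs, 1e-6)
  expect_lt(abs(st$Xr - ref$Xr) / ref$Xr, 1e-6)

  A <- matrix(c(0, -0.02, 0.015, 0), 2, 2)
  cm2 <- make_community(A, gamma_bar = 5e-4)
  p2 <- hgt_params(N = 2)
  ref2 <- rk4_integrate(cm2, c(0.1, 0.1), c(0.05, 0), 0.01, p2,
                        t_end = 40, h = 1e-3)
  tr2 <- integrate_phase(cm2, list(Xs = c(0.1, 0.1), Xr = c(0.05, 0)),
                         c(0, 40), 0.01, p2)
  st2 <- final_state(tr2, p2)
  expect_true(all(abs(st2$Xs - ref2$Xs) / ref2$Xs < 1e-6))
  expect_lt(abs(st2$Xr[1] - ref2$Xr[1]) / ref2$Xr[1], 1e-6)
})

test_that("abundances stay nonnegative and respond monotonically to dose", {
  set.seed(19)
  p <- hgt_params()
  comm <- hgtstab:::draw_community(p, 909)
  st0 <- list(Xs = runif(10, 0, 0.3), Xr = runif(10, 0, 0.1))
  tr <- integrate_phase(comm, st0, seq(0, 525, by = 75), 0.1, p)
  expect_true(all(tr$Xs >= 0) && all(tr$Xr >= 0))
  # larger dose weakly decreases every taxon total derivative at onset
  d_low <- glv_hgt_rhs(st0$Xs, st0$Xr, 0.01, comm, p)
  d_high <- glv_hgt_rhs(st0$Xs, st0$Xr, 0.1, comm, p)
  tot_low <- d_low$dXs + d_low$dXr
  tot_high <- d_high$dXs + d_high$dXr
  expect_true(all(tot_high <= tot_low + 1e-14))
})

test_that("resistant fraction rises under stressor when kill gap exceeds cost", {
  p <- hgt_params(N = 1, gamma_bar = 0)
  cm <- single_taxon_community(r = 0.1, s = 0.1, gamma = 0, c_cost = 0.005)
  # beta_r D + c = 0.015 < beta_s D = 0.1: resistance favoured during exposure
  tr <- integrate_phase(cm, list(Xs = 0.5, Xr = 0.5), c(0, 25), 0.1, p)
  st <- final_state(tr, p)
  expect_gt(st$Xr / (st$Xs + st$Xr), 0.5)
})

test_that("halving integrator tolerances moves reported abundances < 0.1%", {
  set.seed(23)
  p <- hgt_params()
  comm <- hgtstab:::draw_community(p, 1234)
  st0 <- list(Xs = rep(0.1, 10), Xr = rep(0, 10))
  st0$Xr[comm$focal] <- 0.1; st0$Xs[comm$focal] <- 0
  run <- function(pp) {
    tr <- integrate_phase(comm, st0, c(0, 500), 0.01, pp)
    final_state(tr, pp)
  }
  a <- run(p)
  p2 <- p; p2$rtol <- p$rtol / 2; p2$atol <- p$atol / 2
  b <- run(p2)
  expect_true(all(abs(a$Xs - b$Xs) <= 1e-3 * pmax(a$Xs, 1e-6)))
  expect_true(all(abs(a$Xr - b$Xr) <= 1e-3 * pmax(a$Xr, 1e-6)))
})

test_that("segregation loss drains the gene-bearing compartment", {
  p <- hgt_params(N = 1, gamma_bar = 0, delta = 0.01)
  cm <- single_taxon_community(r = 0.1, s = 0.1, gamma = 0, c_cost = 0.005)
  d <- glv_hgt_rhs(0.5, 0.5, 0, cm, p)
  # flux delta * Xr moves cells from resistant to susceptible
  p0 <- hgt_params(N = 1, gamma_bar = 0, delta = 0)
  d0 <- glv_hgt_rhs(0.5, 0.5, 0, cm, p0)
  expect_equal(d$dXs - d0$dXs, 0.01 * 0.5)
  expect_equal(d$dXr - d0$dXr, -0.01 * 0.5)
  # pure-loss variant removes without returning
  pl <- hgt_params(N = 1, gamma_bar = 0, delta = 0.01,
                   segregation_pure_loss = TRUE)
  dl <- glv_hgt_rhs(0.5, 0.5, 0, cm, pl)
  expect_equal(dl$dXs, d0$dXs)
  expect_equal(dl$dXr, d0$dXr - 0.01 * 0.5)
})

test_that("trajectories expose a tidy long-format view", {
  p <- hgt_params(N = 2)
  cm <- make_community(matrix(0, 2, 2), gamma_bar = 1e-3)
  tr <- integrate_phase(cm, list(Xs = c(0.1, 0.2), Xr = c(0.05, 0)),
                        seq(0, 50, by = 10), 0, p)
  df <- trajectory_to_df(tr)
  expect_equal(nrow(df), 6 * 2 * 2)
  expect_setequal(unique(df$compartment), c("susceptible", "resistant"))
  expect_equal(df$abundance[df$time == 0 & df$compartment == "susceptible"],
               c(0.1, 0.2))
})
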
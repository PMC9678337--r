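test_that("parameter validation enforces ranges and the susceptibility order", {
  expect_s3_class(hgt_params(), "hgt_params")
  expect_error(hgt_params(sigma = -0.1), "nonnegative")
  expect_error(hgt_params(C = 1.5), "\\[0, 1\\]")
  expect_error(hgt_params(beta_s = 0.05, beta_r = 0.1), "susceptibility")
})

test_that("interaction sampling follows connectance, half-normal magnitude, and sign law", {
  set.seed(101)
  p <- hgt_params(N = 10, C = 0.7, positivity = 0.5)
  draws <- replicate(200, sample_interactions(p), simplify = FALSE)
  vals <- unlist(lapply(draws, function(A) A[row(A) != col(A)]))
  n_off <- length(vals)
  frac_nonzero <- mean(vals != 0)
  # binomial Monte-Carlo error on 18000 entries ~ 0.0034
  expect_lt(abs(frac_nonzero - 0.7), 4 * sqrt(0.7 * 0.3 / n_off))
  # half-normal mean = sigma * sqrt(2/pi)
  mags <- abs(vals[vals != 0])
  expect_lt(abs(mean(mags) - p$sigma * sqrt(2 / pi)),
            4 * stats::sd(mags) / sqrt(length(mags)))
  expect_true(all(vapply(draws, function(A) all(diag(A) == 0), TRUE)))

  # purely competitive: all present terms strictly negative
  set.seed(102)
  A <- sample_interactions(hgt_params(positivity = 0, C = 1))
  expect_true(all(A[row(A) != col(A)] < 0))
  # no interactions at zero connectance
  expect_equal(sample_interactions(hgt_params(C = 0)), matrix(0, 10, 10))
})

test_that("positive-interaction fraction tracks positivity and is monotone", {
  pm_grid <- c(0, 0.25, 0.5, 0.75, 1)
  frac <- vapply(pm_grid, function(pm) {
    set.seed(500)
    vals <- unlist(replicate(60, {
      A <- sample_interactions(hgt_params(positivity = pm, C = 0.7))
      A[A != 0]
    }, simplify = FALSE))
    mean(vals > 0)
  }, 0)
  n <- 60 * 90 * 0.7
  expect_true(all(abs(frac - pm_grid) < 4 * sqrt(0.25 / n) + 1e-12))
  expect_true(all(diff(frac) >= 0))
})

test_that("growth-rate calibration makes all-ones an exact fixed point", {
  expect_equal(calibrate_growth_rates(matrix(0, 4, 4), 0.1), rep(0.1, 4))
  A <- matrix(0, 2, 2); A[1, 2] <- 0.02
  expect_equal(calibrate_growth_rates(A, 0.1), c(0.08, 0.1))
  # algebraic identity r_i = s - sum_j a_ij to machine precision
  set.seed(7)
  for (i in 1:10) {
    A <- sample_interactions(hgt_params())
    r <- calibrate_growth_rates(A, 0.1)
    expect_true(all(abs(r - 0.1 + rowSums(A)) < 1e-12))
  }
})

test_that("linear stability check matches analytic eigenvalues and dynamics", {
  # noninteracting: Jacobian -s * I, always stable
  expect_true(check_linear_stability(matrix(0, 10, 10), s = 0.1))
  # mutualism stronger than self-limitation: top eigenvalue -s + 0.2 > 0
  A <- matrix(0, 2, 2); A[1, 2] <- A[2, 1] <- 0.2
  expect_false(check_linear_stability(A, s = 0.1))
  # a stable community returns from a small displacement
  set.seed(21)
  p <- hgt_params()
  comm <- hgtstab:::draw_community(p, 5551)
  expect_true(check_linear_stability(comm))
  x0 <- rep(1, 10) * (1 + 0.01 * c(1, -1))
  tr <- integrate_phase(comm, list(Xs = x0, Xr = rep(0, 10)), c(0, 300), 0, p)
  st <- final_state(tr, p)
  expect_true(max(abs(st$Xs - 1)) < 1e-4)
})

test_that("conjugation matrix: mean, truncation at zero, and transfer mask", {
  # immobile gene
  expect_equal(conjugation_matrix(0, matrix(0.3, 2, 2)), matrix(0, 2, 2))
  # empirical mean ~ gamma_bar at 10% relative noise (truncation negligible)
  set.seed(303)
  Z <- matrix(rnorm(1e5), 250, 400)
  G <- conjugation_matrix(5e-4, Z)
  expect_true(all(G >= 0))
  expect_lt(abs(mean(G) - 5e-4) / 5e-4, 4 * 0.1 / sqrt(1e5))
  # strongly negative noise draws are truncated, not carried through
  expect_equal(conjugation_matrix(5e-4, matrix(-50, 1, 1))[1, 1], 0)
  # a zero mask row blocks all transfer into that recipient
  mask <- matrix(1, 3, 3); mask[2, ] <- 0
  A <- matrix(0, 3, 3)
  comm <- make_community(A, gamma_bar = 1e-2, mask = mask, focal = 1L)
  expect_true(all(comm$Gamma[2, ] == 0))
  p <- hgt_params(N = 3, gamma_bar = 1e-2)
  st0 <- list(Xs = c(0, 0.1, 0.1), Xr = c(0.1, 0, 0))
  tr <- integrate_phase(comm, st0, c(0, 200), 0, p)
  expect_true(all(tr$Xr[, 2] == 0))
  expect_gt(max(tr$Xr[, 3]), 0)  # unmasked taxon does receive the gene
})

test_that("ensemble generation is deterministic, stable, and sub-seeded", {
  p <- hgt_params(N = 6)
  e1 <- generate_ensemble(p, 5, seed = 99)
  e2 <- generate_ensemble(p, 5, seed = 99)
  expect_identical(e1, e2)
  expect_true(all(vapply(e1, check_linear_stability, TRUE)))
  # regenerating member 3 alone reproduces it (order independence)
  solo <- hgtstab:::draw_community(p, e1[[3]]$seed, id = 3L)
  expect_identical(solo, e1[[3]])
  # zero connectance: noninteracting members
  e0 <- generate_ensemble(hgt_params(C = 0), 3, seed = 1)
  expect_true(all(vapply(e0, function(cm) all(cm$A == 0), TRUE)))
  # infeasible regime trips the rejection cap
  bad <- hgt_params(N = 8, sigma = 1, positivity = 1, C = 1, max_attempts = 25)
  expect_error(generate_ensemble(bad, 1, seed = 4), "max_attempts")
})
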
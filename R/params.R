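#' Model parameters for the two-compartment gLV-HGT model
#'
#' Bundles the ecological and evolutionary parameters of the simulated
#' microbiomes together with the constants of the perturbation protocol.
#' Defaults are the standard parameter set used throughout the main
#' analyses: 10 taxa, connectance 0.7, half-normal interaction magnitudes
#' with scale 0.015, self-inhibition 0.1, resistance cost 0.005, mean
#' conjugation rate 5e-4 with 10% relative Gaussian noise, adjustment phase
#' of 500 time units (dose 0.01 when prior exposure is simulated), and a
#' perturbation of dose 0.1 lasting 25 time units.
#'
#' @param N Number of taxa.
#' @param C Connectance: probability that any given off-diagonal interaction
#'   term is nonzero.
#' @param sigma Scale of the half-normal distribution from which interaction
#'   magnitudes are drawn (the standard deviation of the underlying normal).
#' @param s Self-inhibition coefficient, shared by all taxa.
#' @param positivity Fraction of nonzero interaction terms that are positive;
#'   0 gives a purely competitive community, 1 a purely cooperative one.
#' @param c_cost Growth-rate cost of carrying the resistance gene.
#' @param gamma_bar Mean per-cell conjugation (gene-transfer) rate.
#' @param gamma_noise_rel Relative standard deviation of the per-pair
#'   conjugation noise: noise sd is \code{gamma_noise_rel * gamma_bar}.
#' @param delta Segregation-loss rate (gene-bearing cells reverting to
#'   gene-free); 0 in the main analyses.
#' @param segregation_pure_loss If \code{TRUE}, segregative loss removes cells
#'   instead of returning them to the gene-free compartment.
#' @param beta_s,beta_r Stressor susceptibility of gene-free and gene-bearing
#'   cells; resistance must not increase susceptibility.
#' @param D_perturb Stressor dose during the perturbation window.
#' @param D_prior Stressor dose during the adjustment phase when prior
#'   exposure is simulated.
#' @param t_adjust,t_perturb Durations of the adjustment and perturbation
#'   phases, in model time units.
#' @param t_recovery Horizon of the optional post-perturbation recovery phase
#'   (stressor-free), used for the return-time metric.
#' @param x0 Initial total abundance of every taxon at the start of the
#'   adjustment phase.
#' @param init_res_frac Initial resistant fraction of the focal taxon in
#'   scenarios where the gene is present.
#' @param extinction_floor Abundances below this value are treated as extinct
#'   at phase boundaries.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param pairwise_presence If \code{TRUE}, interaction presence is sampled
#'   per unordered pair (both \code{a_ij} and \code{a_ji} present or absent
#'   together) instead of per ordered element.
#' @param max_attempts Cap on rejection-sampling attempts per community when
#'   enforcing linear stability of the equilibrium.
#'
#' @return An object of class \code{"hgt_params"} (a validated list).
#' @export
#' @examples
#' p <- hgt_params()
#' p$gamma_bar
hgt_params <- function(N = 10,
                       C = 0.7,
                       sigma = 0.015,
                       s = 0.1,
                       positivity = 0.5,
                       c_cost = 0.005,
                       gamma_bar = 0.5e-3,
                       gamma_noise_rel = 0.1,
                       delta = 0,
                       segregation_pure_loss = FALSE,
                       beta_s = 1,
                       beta_r = 0.1,
                       D_perturb = 0.1,
                       D_prior = 0.01,
                       t_adjust = 500,
                       t_perturb = 25,
                       t_recovery = 500,
                       x0 = 0.1,
                       init_res_frac = 1,
                       extinction_floor = 1e-9,
                       rtol = 1e-8,
                       atol = 1e-10,
                       pairwise_presence = FALSE,
                       max_attempts = 1000L) {
  p <- list(
    N = as.integer(N), C = C, sigma = sigma, s = s, positivity = positivity,
    c_cost = c_cost, gamma_bar = gamma_bar, gamma_noise_rel = gamma_noise_rel,
    delta = delta, segregation_pure_loss = isTRUE(segregation_pure_loss),
    beta_s = beta_s, beta_r = beta_r,
    D_perturb = D_perturb, D_prior = D_prior,
    t_adjust = t_adjust, t_perturb = t_perturb, t_recovery = t_recovery,
    x0 = x0, init_res_frac = init_res_frac,
    extinction_floor = extinction_floor,
    rtol = rtol, atol = atol,
    pairwise_presence = isTRUE(pairwise_presence),
    max_attempts = as.integer(max_attempts)
  )
  class(p) <- "hgt_params"
  validate_params(p)
  p
}

#' @rdname hgt_params
#' @param params Object to validate.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "hgt_params"))
  p <- params
  scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (nm in c("C", "sigma", "s", "positivity", "c_cost", "gamma_bar",
               "gamma_noise_rel", "delta", "beta_s", "beta_r", "D_perturb",
               "D_prior", "t_adjust", "t_perturb", "t_recovery", "x0",
               "init_res_frac", "extinction_floor", "rtol", "atol")) {
    if (!scalar_num(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be nonnegative")
  }
  if (p$N < 1) stop("N must be at least 1")
  for (nm in c("C", "positivity", "init_res_frac")) {
    if (p[[nm]] > 1) stop("parameter '", nm, "' must lie in [0, 1]")
  }
  if (p$beta_r > p$beta_s) {
    stop("beta_r must not exceed beta_s: resistance cannot increase susceptibility")
  }
  if (p$max_attempts < 1) stop("max_attempts must be positive")
  invisible(params)
}

#' @export
print.hgt_params <- function(x, ...) {
  cat("gLV-HGT model parameters\n")
  cat(sprintf("  taxa N = %d, connectance C = %g, positivity = %g\n",
              x$N, x$C, x$positivity))
  cat(sprintf("  interaction scale sigma = %g, self-inhibition s = %g\n",
              x$sigma, x$s))
  cat(sprintf("  gene: cost c = %g, mean transfer rate = %g (noise %g rel.), delta = %g\n",
              x$c_cost, x$gamma_bar, x$gamma_noise_rel, x$delta))
  cat(sprintf("  protocol: adjust t = %g (prior dose %g), perturb D = %g for t = %g\n",
              x$t_adjust, x$D_prior, x$D_perturb, x$t_perturb))
  invisible(x)
}
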
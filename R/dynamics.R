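#' Time derivative of the two-compartment gLV-HGT system
#'
#' For each taxon i the gene-free (susceptible) compartment grows at
#' \code{r_i}, the gene-bearing (resistant) compartment at \code{r_i - c};
#' both are limited by self-inhibition \code{s_i} acting on the taxon's total
#' abundance and influenced by every partner taxon's total abundance through
#' the interaction matrix. Conjugation moves gene-free cells of taxon i into
#' its gene-bearing compartment at the mass-action rate
#' \code{sum_j gamma_ij * Xs_i * Xr_j}. A stressor at dose D kills the two
#' compartments at rates \code{beta_s * D} and \code{beta_r * D}. With
#' \code{delta > 0}, gene-bearing cells revert (segregation loss) at rate
#' \code{delta}, returning to the gene-free compartment unless pure loss is
#' requested.
#'
#' @param Xs,Xr Length-N abundance vectors of the gene-free and gene-bearing
#'   compartments.
#' @param D Stressor dose.
#' @param community An \code{hgt_community}.
#' @param params An \code{\link{hgt_params}} object.
#' @return List with elements \code{dXs} and \code{dXr}.
#' @export
glv_hgt_rhs <- function(Xs, Xr, D, community, params) {
  N <- nrow(community$A)
  if (length(Xs) != N || length(Xr) != N) {
    stop("state dimension does not match community size")
  }
  total <- Xs + Xr
  growth <- community$r_vec - community$s_vec * total +
    as.vector(community$A %*% total)
  transfer <- Xs * as.vector(community$Gamma %*% Xr)
  dXs <- Xs * growth - transfer - params$beta_s * D * Xs
  dXr <- Xr * (growth - community$c) + transfer - params$beta_r * D * Xr
  if (params$delta > 0) {
    loss <- params$delta * Xr
    dXr <- dXr - loss
    if (!params$segregation_pure_loss) dXs <- dXs + loss
  }
  list(dXs = dXs, dXr = dXr)
}

# deSolve-facing wrapper: y = c(Xs, Xr)
rhs_desolve <- function(t, y, parms) {
  N <- parms$N
  Xs <- y[seq_len(N)]
  Xr <- y[N + seq_len(N)]
  d <- glv_hgt_rhs(Xs, Xr, parms$D, parms$community, parms$params)
  list(c(d$dXs, d$dXr))
}

#' Integrate community dynamics at a constant stressor dose
#'
#' Solves the two-compartment system with a stiff-capable adaptive
#' integrator (\code{deSolve::ode}, lsoda) at tight default tolerances
#' (rtol 1e-8, atol 1e-10). The dose is constant over the span; the
#' experiment protocol chains phases with state handoff.
#'
#' @param community An \code{hgt_community}.
#' @param state List with vectors \code{Xs} and \code{Xr} (initial state).
#' @param times Increasing vector of report times (first element is the
#'   initial time).
#' @param D Stressor dose over the span.
#' @param params An \code{\link{hgt_params}} object.
#' @return Object of class \code{"hgt_trajectory"}: list with \code{times},
#'   \code{Xs} and \code{Xr} (rows = time points), and \code{D}.
#' @export
integrate_phase <- function(community, state, times, D, params) {
  N <- nrow(community$A)
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  y0 <- c(state$Xs, state$Xr)
  stopifnot(all(y0 >= 0), D >= 0)
  sol <- deSolve::ode(
    y = y0, times = times, func = rhs_desolve,
    parms = list(N = N, D = D, community = community, params = params),
    method = "lsoda", rtol = params$rtol, atol = params$atol
  )
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("ODE integration failed (istate = ", diagn[1], ")")
  }
  if (nrow(sol) < length(times)) {
    stop("ODE integration stopped early at t = ", sol[nrow(sol), 1])
  }
  out <- list(
    times = sol[, 1],
    Xs = pmax(unname(sol[, 1 + seq_len(N), drop = FALSE]), 0),
    Xr = pmax(unname(sol[, 1 + N + seq_len(N), drop = FALSE]), 0),
    D = D
  )
  class(out) <- "hgt_trajectory"
  out
}

#' Final state of a trajectory, with the extinction floor applied
#'
#' Abundances below the extinction floor are set to exactly zero, so
#' numerically tiny populations cannot revive in a later phase.
#'
#' @param trajectory An \code{hgt_trajectory}.
#' @param params An \code{\link{hgt_params}} object.
#' @return List with vectors \code{Xs} and \code{Xr}.
#' @export
final_state <- function(trajectory, params) {
  n <- length(trajectory$times)
  Xs <- trajectory$Xs[n, ]
  Xr <- trajectory$Xr[n, ]
  Xs[Xs < params$extinction_floor] <- 0
  Xr[Xr < params$extinction_floor] <- 0
  list(Xs = Xs, Xr = Xr)
}

#' Tidy data frame view of a trajectory
#'
#' @param trajectory An \code{hgt_trajectory}.
#' @return Data frame with columns \code{time}, \code{taxon},
#'   \code{compartment} ("susceptible"/"resistant") and \code{abundance}.
#' @export
trajectory_to_df <- function(trajectory) {
  N <- ncol(trajectory$Xs)
  nt <- length(trajectory$times)
  data.frame(
    time = rep(trajectory$times, times = 2 * N),
    taxon = rep(rep(seq_len(N), each = nt), times = 2),
    compartment = rep(c("susceptible", "resistant"), each = nt * N),
    abundance = c(as.vector(trajectory$Xs), as.vector(trajectory$Xr))
  )
}
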
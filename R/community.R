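#' Sample a signed interaction matrix
#'
#' Each off-diagonal element \code{a_ij} (the per-capita effect of taxon j on
#' taxon i) is present independently with probability \code{C}; present
#' magnitudes are drawn from a half-normal distribution with scale
#' \code{sigma}, and each present term is positive with probability
#' \code{positivity}, negative otherwise. The diagonal is zero:
#' self-limitation is carried separately by the self-inhibition coefficient.
#'
#' With \code{pairwise_presence = TRUE} presence is decided per unordered
#' pair, so \code{a_ij} and \code{a_ji} are jointly present or absent (signs
#' and magnitudes still independent).
#'
#' @param params An \code{\link{hgt_params}} object.
#' @return An \code{N x N} numeric matrix with zero diagonal.
#' @export
sample_interactions <- function(params) {
  validate_params(params)
  N <- params$N
  A <- matrix(0, N, N)
  if (N == 1) return(A)
  off <- which(row(A) != col(A))
  if (params$pairwise_presence) {
    pres_pair <- matrix(FALSE, N, N)
    upper <- which(upper.tri(pres_pair))
    pres_pair[upper] <- stats::runif(length(upper)) < params$C
    pres_pair <- pres_pair | t(pres_pair)
    present <- pres_pair[off]
  } else {
    present <- stats::runif(length(off)) < params$C
  }
  n_on <- sum(present)
  if (n_on > 0) {
    mag <- abs(stats::rnorm(n_on, 0, params$sigma))
    sgn <- ifelse(stats::runif(n_on) < params$positivity, 1, -1)
    A[off[present]] <- sgn * mag
  }
  A
}

#' Calibrate intrinsic growth rates to an all-ones equilibrium
#'
#' Chooses growth rates so that the gene-free, stressor-free system has a
#' fixed point with every taxon at abundance 1: substituting \code{X_j = 1}
#' into the growth equation gives \code{r_i = s_i - sum_j a_ij}. Taxa that
#' receive much cooperation are assigned low intrinsic growth (and vice
#' versa), which prevents explosive dynamics in highly cooperative
#' communities.
#'
#' @param A Interaction matrix with zero diagonal.
#' @param s Self-inhibition, a scalar or length-N vector.
#' @return Numeric vector of intrinsic growth rates.
#' @export
calibrate_growth_rates <- function(A, s) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(diag(A) == 0))
  rep_len(s, nrow(A)) - rowSums(A)
}

#' Linear stability of the all-ones equilibrium
#'
#' Tests whether the calibrated, gene-free, stressor-free community is
#' linearly asymptotically stable at the all-ones state. The Jacobian there
#' is \code{A - diag(s)}; stability requires every eigenvalue to have a
#' strictly negative real part.
#'
#' @param community An \code{hgt_community} object, or an interaction matrix
#'   if \code{s} is also given.
#' @param s Self-inhibition vector (only when \code{community} is a matrix).
#' @return \code{TRUE} if stable, else \code{FALSE}.
#' @export
check_linear_stability <- function(community, s = NULL) {
  if (inherits(community, "hgt_community")) {
    A <- community$A
    s <- community$s_vec
  } else {
    A <- community
    stopifnot(!is.null(s))
    s <- rep_len(s, nrow(A))
  }
  J <- A
  diag(J) <- -s
  all(Re(eigen(J, only.values = TRUE)$values) < 0)
}

#' Conjugation-rate matrix from a standard-normal noise matrix
#'
#' The per-cell transfer rate from donor taxon j into recipient taxon i is
#' \code{gamma_ij = gamma_bar * (1 + gamma_noise_rel * Z_ij)}, truncated at
#' zero, where \code{Z_ij} is standard normal. Transfer occurs both within a
#' taxon (diagonal) and between taxa. An optional binary mask zeroes
#' forbidden donor-recipient routes, modelling host-range or spatial
#' constraints on conjugation.
#'
#' @param gamma_bar Mean conjugation rate.
#' @param Z \code{N x N} standard-normal noise matrix.
#' @param gamma_noise_rel Relative noise sd (default 0.1).
#' @param mask Optional \code{N x N} 0/1 matrix; entries where the mask is 0
#'   are forced to 0.
#' @return Nonnegative \code{N x N} conjugation-rate matrix.
#' @export
conjugation_matrix <- function(gamma_bar, Z, gamma_noise_rel = 0.1, mask = NULL) {
  stopifnot(gamma_bar >= 0, is.matrix(Z))
  G <- pmax(gamma_bar * (1 + gamma_noise_rel * Z), 0)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(Z)))
    G <- G * (mask != 0)
  }
  G
}

#' Draw a conjugation-rate matrix
#'
#' Convenience wrapper around \code{\link{conjugation_matrix}} that draws the
#' noise matrix from the current RNG stream.
#'
#' @inheritParams sample_interactions
#' @param mask Optional binary transfer-permission matrix.
#' @export
sample_conjugation_matrix <- function(params, mask = NULL) {
  validate_params(params)
  Z <- matrix(stats::rnorm(params$N^2), params$N, params$N)
  conjugation_matrix(params$gamma_bar, Z, params$gamma_noise_rel, mask)
}

new_community <- function(A, s_vec, r_vec, Z, gamma_bar, gamma_noise_rel,
                          c_cost, focal, seed = NA_integer_, mask = NULL,
                          id = NA_integer_) {
  comm <- list(
    A = A, s_vec = s_vec, r_vec = r_vec,
    Z = Z, gamma_bar = gamma_bar, gamma_noise_rel = gamma_noise_rel,
    Gamma = conjugation_matrix(gamma_bar, Z, gamma_noise_rel, mask),
    mask = mask, c = c_cost, focal = as.integer(focal),
    seed = as.integer(seed), id = as.integer(id)
  )
  class(comm) <- "hgt_community"
  comm
}

#' Rescale a community's mean conjugation rate
#'
#' Rebuilds the conjugation-rate matrix at a new mean rate while keeping the
#' community's stored noise matrix, so mobility sweeps can reuse the same
#' ensemble across grid cells (common random numbers).
#'
#' @param community An \code{hgt_community}.
#' @param gamma_bar New mean conjugation rate.
#' @return The community with \code{Gamma} (and \code{gamma_bar}) replaced.
#' @export
set_gamma_bar <- function(community, gamma_bar) {
  stopifnot(inherits(community, "hgt_community"), gamma_bar >= 0)
  community$gamma_bar <- gamma_bar
  community$Gamma <- conjugation_matrix(gamma_bar, community$Z,
                                        community$gamma_noise_rel,
                                        community$mask)
  community
}

draw_community <- function(params, seed, mask = NULL, id = NA_integer_) {
  set.seed(seed)
  for (attempt in seq_len(params$max_attempts)) {
    A <- sample_interactions(params)
    r <- calibrate_growth_rates(A, params$s)
    if (check_linear_stability(A, params$s)) {
      Z <- matrix(stats::rnorm(params$N^2), params$N, params$N)
      focal <- sample.int(params$N, 1)
      return(new_community(A, rep_len(params$s, params$N), r, Z,
                           params$gamma_bar, params$gamma_noise_rel,
                           params$c_cost, focal, seed, mask, id))
    }
  }
  stop("community rejection rate exceeded max_attempts = ", params$max_attempts,
       "; parameter regime appears infeasible")
}

#' Generate an ensemble of stable model communities
#'
#' Draws independent random communities, calibrates their growth rates to the
#' all-ones equilibrium, and rejection-samples until each draw is linearly
#' asymptotically stable there. Each community gets its own deterministic
#' sub-seed derived from \code{seed}, so ensembles are reproducible and
#' individual members can be regenerated in isolation (results do not depend
#' on generation order or worker count). The focal taxon — the initial
#' carrier of the resistance gene — is chosen uniformly at random per
#' community.
#'
#' @inheritParams sample_interactions
#' @param n_communities Ensemble size.
#' @param seed Top-level integer seed.
#' @param mask Optional binary conjugation mask applied to every member.
#' @return A list of \code{hgt_community} objects (class
#'   \code{"hgt_ensemble"}).
#' @export
generate_ensemble <- function(params, n_communities, seed, mask = NULL) {
  validate_params(params)
  stopifnot(n_communities >= 1)
  seeds <- community_seeds(seed, n_communities)
  ens <- lapply(seq_len(n_communities), function(i) {
    draw_community(params, seeds[i], mask, id = i)
  })
  class(ens) <- c("hgt_ensemble", "list")
  attr(ens, "seed") <- as.integer(seed)
  ens
}

# Deterministic per-community sub-seeds: a fixed-multiplier congruential hop
# from the top-level seed, kept inside the signed 32-bit range.
community_seeds <- function(seed, n) {
  (as.integer(seed) + 48271 * seq_len(n)) %% .Machine$integer.max
}

#' @export
print.hgt_community <- function(x, ...) {
  cat(sprintf("gLV-HGT community: %d taxa, focal taxon %d\n", nrow(x$A), x$focal))
  cat(sprintf("  nonzero interactions: %d, gamma_bar = %g, cost = %g\n",
              sum(x$A != 0), x$gamma_bar, x$c))
  invisible(x)
}
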
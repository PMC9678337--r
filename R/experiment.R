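#' Scenario specification for the perturbation protocol
#'
#' The protocol crosses two factors: whether the focal taxon initially
#' carries the resistance gene, and whether the community adjusts in the
#' presence of a low stressor dose (prior exposure). Labels follow the
#' convention S/R for susceptible/resistant and naive/exposed for the
#' adjustment environment.
#'
#' @param has_resistance Does the focal taxon start with the gene?
#' @param prior_exposure Does the adjustment phase use the low prior dose?
#' @return An \code{hgt_scenario} with a canonical \code{label}.
#' @export
scenario_spec <- function(has_resistance, prior_exposure) {
  label <- paste0(if (has_resistance) "R" else "S",
                  if (prior_exposure) "-exposed" else "-naive")
  structure(list(has_resistance = isTRUE(has_resistance),
                 prior_exposure = isTRUE(prior_exposure),
                 label = label),
            class = "hgt_scenario")
}

#' The four canonical scenarios
#' @return Named list of \code{hgt_scenario} objects, in the order
#'   S-naive, S-exposed, R-naive, R-exposed.
#' @export
scenario_quartet <- function() {
  specs <- list(scenario_spec(FALSE, FALSE), scenario_spec(FALSE, TRUE),
                scenario_spec(TRUE, FALSE), scenario_spec(TRUE, TRUE))
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Initial state for a scenario
#'
#' Every taxon starts at the same total abundance \code{params$x0}, well
#' below the calibrated equilibrium at 1, so the adjustment phase performs a
#' genuine community assembly. In R-scenarios a fraction
#' \code{params$init_res_frac} (default all) of the focal taxon's abundance
#' is placed in the gene-bearing compartment; all other taxa start gene-free.
#'
#' @param community An \code{hgt_community}.
#' @param spec An \code{hgt_scenario}.
#' @param params An \code{\link{hgt_params}} object.
#' @return List with vectors \code{Xs}, \code{Xr}.
#' @export
initial_state <- function(community, spec, params) {
  N <- nrow(community$A)
  Xs <- rep(params$x0, N)
  Xr <- rep(0, N)
  if (spec$has_resistance) {
    f <- community$focal
    Xr[f] <- params$x0 * params$init_res_frac
    Xs[f] <- params$x0 - Xr[f]
  }
  list(Xs = Xs, Xr = Xr)
}

res_freq <- function(Xs, Xr, floor) {
  total <- Xs + Xr
  out <- Xr / total
  out[total < floor] <- NA_real_
  out
}

#' Run one perturbation scenario
#'
#' Phase 1 (adjustment): integrate for \code{t_adjust} at dose
#' \code{D_prior} if the scenario has prior exposure, else stressor-free;
#' record each taxon's total abundance and resistance frequency at the phase
#' boundary (the instant before the perturbation). Phase 2 (perturbation):
#' integrate for \code{t_perturb} at dose \code{D_perturb}; record the same
#' quantities at the end of the window. Optionally, phase 3 (recovery):
#' integrate stressor-free for \code{t_recovery} to support the return-time
#' metric.
#'
#' @param community A calibrated \code{hgt_community}.
#' @param spec An \code{hgt_scenario}.
#' @param params An \code{\link{hgt_params}} object.
#' @param keep_trajectory Retain full trajectories (sampled at
#'   \code{n_report} points per phase)?
#' @param recovery Run the stressor-free recovery phase?
#' @param n_report Report points per phase when trajectories are kept.
#' @return An \code{hgt_scenario_result}: pre/post abundance vectors
#'   (\code{A_before}, \code{A_after}), resistance frequencies, and
#'   optionally the trajectories.
#' @export
run_scenario <- function(community, spec, params,
                         keep_trajectory = FALSE, recovery = FALSE,
                         n_report = 201) {
  state <- initial_state(community, spec, params)
  D_adjust <- if (spec$prior_exposure) params$D_prior else 0
  grid <- function(t0, t1) {
    if (keep_trajectory || recovery) seq(t0, t1, length.out = n_report)
    else c(t0, t1)
  }
  res <- tryCatch({
    tr1 <- integrate_phase(community, state, grid(0, params$t_adjust),
                           D_adjust, params)
    st1 <- final_state(tr1, params)
    tr2 <- integrate_phase(community, st1,
                           grid(params$t_adjust,
                                params$t_adjust + params$t_perturb),
                           params$D_perturb, params)
    st2 <- final_state(tr2, params)
    tr3 <- NULL
    if (recovery) {
      t2 <- params$t_adjust + params$t_perturb
      tr3 <- integrate_phase(community, st2, grid(t2, t2 + params$t_recovery),
                             0, params)
    }
    list(tr1 = tr1, st1 = st1, tr2 = tr2, st2 = st2, tr3 = tr3)
  }, error = function(e) {
    stop("scenario ", spec$label, ": ", conditionMessage(e), call. = FALSE)
  })
  fl <- params$extinction_floor
  out <- list(
    label = spec$label,
    community_id = community$id,
    A_before = res$st1$Xs + res$st1$Xr,
    A_after = res$st2$Xs + res$st2$Xr,
    resistance_freq_before = res_freq(res$st1$Xs, res$st1$Xr, fl),
    resistance_freq_after = res_freq(res$st2$Xs, res$st2$Xr, fl),
    trajectory = if (keep_trajectory) list(adjust = res$tr1, perturb = res$tr2,
                                           recovery = res$tr3) else NULL,
    recovery_trajectory = res$tr3
  )
  class(out) <- "hgt_scenario_result"
  out
}

#' Run all four scenarios on one community
#'
#' Runs the full 2x2 protocol on the same community object, so the
#' resistance and exposure contrasts are paired within-community
#' differences.
#'
#' @inheritParams run_scenario
#' @param reuse Optional named list of already-computed scenario results to
#'   reuse (e.g. the gene-free scenarios, which do not depend on the
#'   conjugation-rate matrix, when sweeping gene mobility).
#' @return Named list of four \code{hgt_scenario_result}s
#'   (class \code{"hgt_quartet"}).
#' @export
run_quartet <- function(community, params, keep_trajectory = FALSE,
                        recovery = FALSE, reuse = NULL) {
  specs <- scenario_quartet()
  out <- lapply(specs, function(sp) {
    if (!is.null(reuse) && sp$label %in% names(reuse)) return(reuse[[sp$label]])
    run_scenario(community, sp, params, keep_trajectory, recovery)
  })
  class(out) <- c("hgt_quartet", "list")
  out
}

#' Abundance-weighted resistance frequency over a taxon subset
#'
#' Computes \code{sum(Xr) / sum(Xs + Xr)} over the subset, the
#' population-level fraction of gene-bearing cells (e.g. within the
#' background community).
#'
#' @param result An \code{hgt_scenario_result} produced with trajectories, or
#'   any object with abundance vectors; here frequencies are recomputed from
#'   \code{A_before} and \code{resistance_freq_before}.
#' @param subset Integer taxon indices.
#' @param when \code{"before"} or \code{"after"} the perturbation.
#' @return Scalar frequency in [0, 1], or \code{NA} if the subset's total
#'   abundance is zero.
#' @export
subset_resistance_freq <- function(result, subset, when = c("before", "after")) {
  when <- match.arg(when)
  A <- if (when == "before") result$A_before else result$A_after
  f <- if (when == "before") result$resistance_freq_before
       else result$resistance_freq_after
  A <- A[subset]; f <- f[subset]
  keep <- !is.na(f)
  if (!any(keep) || sum(A[keep]) <= 0) return(NA_real_)
  sum(A[keep] * f[keep]) / sum(A[keep])
}
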
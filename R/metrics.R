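#' Per-taxon stability across a perturbation
#'
#' Stability of taxon i is the log10 fold change in its total abundance
#' across the perturbation window, \code{log10(A_after / A_before)}, with
#' positive values set to zero so that 0 means unaffected and more negative
#' values mean less stable. Taxa already extinct before the perturbation
#' (below the floor) are recorded as missing; taxa driven extinct by the
#' perturbation get the finite value \code{log10(floor / A_before)} rather
#' than -Inf, so community means stay defined and remain monotone in
#' severity.
#'
#' @param A_before,A_after Nonnegative abundance vectors of equal length.
#' @param floor Extinction floor (abundances below it count as extinct).
#' @return Numeric vector of stabilities in (-Inf, 0], with \code{NA} for
#'   taxa extinct before the perturbation.
#' @export
stability_per_taxon <- function(A_before, A_after, floor = 1e-9) {
  if (length(A_before) != length(A_after)) {
    stop("A_before and A_after must have the same length")
  }
  stopifnot(all(A_before >= 0), all(A_after >= 0))
  out <- pmin(0, log10(pmax(A_after, floor) / A_before))
  out[A_before < floor] <- NA_real_
  out
}

#' Community robustness: mean stability over a taxon subset
#'
#' @param per_taxon Vector of per-taxon stabilities (may contain \code{NA}
#'   for extinct-before taxa, which are excluded).
#' @param subset Integer indices of the taxa to average over (default all).
#' @return Scalar mean stability (<= 0).
#' @export
robustness <- function(per_taxon, subset = seq_along(per_taxon)) {
  vals <- per_taxon[subset]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no non-missing taxa in subset")
  mean(vals)
}

#' Stability report for one scenario
#'
#' Bundles the per-taxon stabilities with the three aggregate robustness
#' values: the whole community, the background community (all taxa except
#' the focal), and the focal taxon alone. Optionally adds the two
#' complementary stability metrics — Bray-Curtis dissimilarity between the
#' pre- and post-perturbation composition, and the time for the community to
#' return to its pre-perturbation state.
#'
#' @param result An \code{hgt_scenario_result}.
#' @param focal Focal taxon index.
#' @param params An \code{\link{hgt_params}} object (for the floor).
#' @param return_time_tol Relative tolerance of the return-time criterion.
#' @return An \code{hgt_stability_report}.
#' @export
stability_report <- function(result, focal, params,
                             return_time_tol = 0.05) {
  fl <- params$extinction_floor
  st <- stability_per_taxon(result$A_before, result$A_after, fl)
  background <- setdiff(seq_along(st), focal)
  rt <- NA_real_
  if (!is.null(result$recovery_trajectory)) {
    rt <- return_time(result$recovery_trajectory, result$A_before,
                      tol = return_time_tol, floor = fl)
  }
  structure(list(
    label = result$label,
    community_id = result$community_id,
    per_taxon = st,
    whole = robustness(st),
    background = robustness(st, background),
    focal = if (is.na(st[focal])) NA_real_ else st[focal],
    n_missing = sum(is.na(st)),
    bray_curtis = bray_curtis(result$A_before, result$A_after),
    return_time = rt
  ), class = "hgt_stability_report")
}

#' Paired stability contrasts from a scenario quartet
#'
#' The resistance contrast dR is the robustness with the gene minus without,
#' in the naive (unexposed) environment: \code{R-naive - S-naive}. The
#' exposure contrast dE is the robustness with prior low-level exposure
#' minus without, for gene-carrying communities:
#' \code{R-exposed - R-naive}. Both are computed at all three scopes (whole
#' community, background, focal). The exposure contrast for fully
#' susceptible communities (\code{S-exposed - S-naive}) is reported
#' alongside as \code{dE_sus_*}.
#'
#' @param quartet An \code{hgt_quartet} (see \code{\link{run_quartet}}).
#' @param community The community the quartet was run on.
#' @param params An \code{\link{hgt_params}} object.
#' @return An \code{hgt_delta_metrics} list with the six primary deltas,
#'   the susceptible-pair exposure deltas, and per-scenario robustness.
#' @export
delta_metrics <- function(quartet, community, params) {
  labs <- c("S-naive", "S-exposed", "R-naive", "R-exposed")
  stopifnot(all(labs %in% names(quartet)))
  ids <- vapply(quartet[labs], function(q) as.character(q$community_id), "")
  if (length(unique(ids)) > 1) {
    stop("quartet mixes results from different communities")
  }
  reports <- lapply(quartet[labs], stability_report,
                    focal = community$focal, params = params)
  rob <- function(lab, scope) reports[[lab]][[scope]]
  scopes <- c("whole", "background", "focal")
  dR <- vapply(scopes, function(sc) rob("R-naive", sc) - rob("S-naive", sc), 0)
  dE <- vapply(scopes, function(sc) rob("R-exposed", sc) - rob("R-naive", sc), 0)
  dEs <- vapply(scopes, function(sc) rob("S-exposed", sc) - rob("S-naive", sc), 0)
  structure(list(
    community_id = community$id,
    dR_whole = dR[["whole"]], dR_background = dR[["background"]],
    dR_focal = dR[["focal"]],
    dE_whole = dE[["whole"]], dE_background = dE[["background"]],
    dE_focal = dE[["focal"]],
    dE_sus_whole = dEs[["whole"]], dE_sus_background = dEs[["background"]],
    dE_sus_focal = dEs[["focal"]],
    reports = reports
  ), class = "hgt_delta_metrics")
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \code{sum |x_i - y_i| / sum (x_i + y_i)}: 0 for identical composition,
#' 1 for disjoint support. Computed on absolute abundances (the model tracks
#' absolute, not relative, abundance); set \code{relative = TRUE} to
#' normalise each vector to proportions first.
#'
#' @param x,y Nonnegative vectors of equal length, not both all-zero.
#' @param relative Normalise to relative abundances first?
#' @return Scalar in [0, 1].
#' @export
bray_curtis <- function(x, y, relative = FALSE) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (relative) {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  denom <- sum(x + y)
  if (denom == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / denom
}

#' Time for the community to return to its pre-perturbation state
#'
#' Scans the recovery-phase trajectory for the first time (relative to the
#' end of the perturbation) at which every non-extinct taxon's total
#' abundance is within \code{tol} (relative) of its pre-perturbation
#' reference, and stays within for the remainder of the horizon. Taxa whose
#' reference is below the floor are excluded; if a taxon is extinct at the
#' end of the horizon while its reference is not, recovery is impossible and
#' the result is missing.
#'
#' @param trajectory Recovery-phase \code{hgt_trajectory} (starts at the end
#'   of the perturbation).
#' @param reference Pre-perturbation abundance vector.
#' @param tol Relative tolerance (default 5%).
#' @param floor Extinction floor.
#' @return Time in model units, or \code{NA} if the community never returns
#'   within the horizon.
#' @export
return_time <- function(trajectory, reference, tol = 0.05, floor = 1e-9) {
  total <- trajectory$Xs + trajectory$Xr
  alive <- reference >= floor
  if (!any(alive)) return(NA_real_)
  relerr <- abs(sweep(total[, alive, drop = FALSE], 2, reference[alive], "/") - 1)
  ok <- apply(relerr <= tol, 1, all)
  # require the community to stay within tolerance once returned
  stays <- rev(cumprod(rev(ok))) > 0
  if (!any(stays)) return(NA_real_)
  trajectory$times[which(stays)[1]] - trajectory$times[1]
}

#' @export
print.hgt_stability_report <- function(x, ...) {
  cat(sprintf("stability report [%s]: whole %.4f, background %.4f, focal %.4f\n",
              x$label, x$whole, x$background, x$focal))
  cat(sprintf("  Bray-Curtis %.4f, return time %s, missing taxa %d\n",
              x$bray_curtis,
              ifelse(is.na(x$return_time), "NA", format(x$return_time)),
              x$n_missing))
  invisible(x)
}
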
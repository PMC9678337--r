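#' Delta metrics and resistance-frequency readouts for one community
#'
#' Runs the four-scenario protocol and returns one row of per-community
#' results: the six paired stability contrasts, the susceptible-pair
#' exposure contrasts, the per-scenario robustness at each scope, and the
#' abundance-weighted background resistance frequency immediately before the
#' perturbation in the naive and exposed gene-carrying scenarios.
#'
#' @param community An \code{hgt_community}.
#' @param params An \code{\link{hgt_params}} object.
#' @param reuse Optional precomputed scenario results (see
#'   \code{\link{run_quartet}}).
#' @return One-row data frame.
#' @export
community_deltas <- function(community, params, reuse = NULL) {
  quartet <- run_quartet(community, params, reuse = reuse)
  dm <- delta_metrics(quartet, community, params)
  background <- setdiff(seq_len(nrow(community$A)), community$focal)
  data.frame(
    community_id = community$id,
    focal = community$focal,
    dR_whole = dm$dR_whole, dR_background = dm$dR_background,
    dR_focal = dm$dR_focal,
    dE_whole = dm$dE_whole, dE_background = dm$dE_background,
    dE_focal = dm$dE_focal,
    dE_sus_whole = dm$dE_sus_whole,
    dE_sus_background = dm$dE_sus_background,
    dE_sus_focal = dm$dE_sus_focal,
    rob_whole_S_naive = dm$reports[["S-naive"]]$whole,
    rob_whole_R_naive = dm$reports[["R-naive"]]$whole,
    rob_whole_R_exposed = dm$reports[["R-exposed"]]$whole,
    bc_S_naive = dm$reports[["S-naive"]]$bray_curtis,
    bc_R_naive = dm$reports[["R-naive"]]$bray_curtis,
    bc_R_exposed = dm$reports[["R-exposed"]]$bray_curtis,
    bg_freq_naive = subset_resistance_freq(quartet[["R-naive"]], background),
    bg_freq_exposed = subset_resistance_freq(quartet[["R-exposed"]], background)
  )
}

# Gene-free scenarios do not depend on the conjugation-rate matrix, so when
# only gamma_bar varies across cells they are computed once per community.
susceptible_pair <- function(community, params) {
  list(
    "S-naive" = run_scenario(community, scenario_spec(FALSE, FALSE), params),
    "S-exposed" = run_scenario(community, scenario_spec(FALSE, TRUE), params)
  )
}

#' Sweep resistance-gene mobility
#'
#' Evaluates the paired stability contrasts across a grid of mean
#' conjugation rates. By default the same community ensemble is reused at
#' every grid point (common random numbers): each community's stored
#' conjugation-noise matrix is rescaled to the cell's mean rate, and the
#' gene-free scenarios are computed once per community. Set
#' \code{paired = FALSE} to draw an independent ensemble per cell.
#'
#' @param params An \code{\link{hgt_params}} object. For the noninteracting
#'   regime pass \code{hgt_params(C = 0)}.
#' @param gamma_grid Vector of mean conjugation rates (typically log-spaced
#'   over 1e-6 to 1e-2).
#' @param n_communities Ensemble size per cell.
#' @param seed Top-level seed.
#' @param paired Reuse one ensemble across cells?
#' @return An \code{hgt_sweep}: list with \code{cells} (per-community rows,
#'   one per community x grid point) and \code{stats} (per-cell mean/sd, see
#'   \code{\link{aggregate_cells}}).
#' @export
sweep_mobility <- function(params, gamma_grid, n_communities, seed,
                           paired = TRUE) {
  validate_params(params)
  stopifnot(length(gamma_grid) >= 1, all(gamma_grid >= 0))
  rows <- list()
  if (paired) {
    ens <- generate_ensemble(params, n_communities, seed)
    sus <- lapply(ens, susceptible_pair, params = params)
    for (g in gamma_grid) {
      for (i in seq_along(ens)) {
        comm <- set_gamma_bar(ens[[i]], g)
        row <- community_deltas(comm, params, reuse = sus[[i]])
        row$gamma_bar <- g
        rows[[length(rows) + 1L]] <- row
      }
    }
  } else {
    cell_seeds <- community_seeds(seed, length(gamma_grid))
    for (k in seq_along(gamma_grid)) {
      g <- gamma_grid[k]
      p_cell <- params
      p_cell$gamma_bar <- g
      ens <- generate_ensemble(p_cell, n_communities, cell_seeds[k])
      for (comm in ens) {
        row <- community_deltas(comm, p_cell)
        row$gamma_bar <- g
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  cells <- do.call(rbind, rows)
  cells$positivity <- params$positivity
  new_sweep(cells, seed, params)
}

#' Sweep interaction positivity by gene mobility
#'
#' Full factorial grid over the fraction of positive interaction terms
#' (community type, from purely competitive at 0 to purely cooperative at 1)
#' and mean conjugation rate. A fresh ensemble is drawn for each positivity
#' value (the interaction structure changes); within a positivity row the
#' ensemble is reused across mobility cells as in
#' \code{\link{sweep_mobility}}.
#'
#' @inheritParams sweep_mobility
#' @param pm_grid Vector of positivity values in [0, 1].
#' @return An \code{hgt_sweep}.
#' @export
sweep_positivity_by_mobility <- function(params, pm_grid, gamma_grid,
                                         n_communities, seed, paired = TRUE) {
  validate_params(params)
  stopifnot(all(pm_grid >= 0), all(pm_grid <= 1))
  pm_seeds <- (community_seeds(seed, length(pm_grid)) + 7919L) %%
    .Machine$integer.max
  parts <- lapply(seq_along(pm_grid), function(k) {
    p_pm <- params
    p_pm$positivity <- pm_grid[k]
    sw <- sweep_mobility(p_pm, gamma_grid, n_communities, pm_seeds[k],
                         paired = paired)
    sw$cells
  })
  cells <- do.call(rbind, parts)
  new_sweep(cells, seed, params)
}

new_sweep <- function(cells, seed, params) {
  structure(list(cells = cells, stats = aggregate_cells(cells),
                 seed = as.integer(seed), params = params),
            class = "hgt_sweep")
}

#' Aggregate per-community sweep rows into per-cell statistics
#'
#' For every (positivity, gamma_bar) cell, the ensemble mean and sample
#' standard deviation of each metric, with the count of missing values.
#'
#' @param cells Data frame of per-community rows (from a sweep).
#' @return Data frame with one row per cell x metric: columns
#'   \code{positivity}, \code{gamma_bar}, \code{metric}, \code{mean},
#'   \code{sd}, \code{n}, \code{n_missing}.
#' @export
aggregate_cells <- function(cells) {
  stopifnot(nrow(cells) >= 1)
  metrics <- setdiff(names(cells),
                     c("community_id", "focal", "gamma_bar", "positivity"))
  key <- interaction(cells$positivity, cells$gamma_bar, drop = TRUE)
  out <- lapply(split(cells, key), function(d) {
    data.frame(
      positivity = d$positivity[1],
      gamma_bar = d$gamma_bar[1],
      metric = metrics,
      mean = vapply(metrics, function(m) mean(d[[m]], na.rm = TRUE), 0),
      sd = vapply(metrics, function(m) stats::sd(d[[m]], na.rm = TRUE), 0),
      n = nrow(d),
      n_missing = vapply(metrics, function(m) sum(is.na(d[[m]])), 0L),
      row.names = NULL
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$positivity, out$gamma_bar, out$metric), ]
}

#' Extract one metric's per-cell means from a sweep
#'
#' @param sweep An \code{hgt_sweep}.
#' @param metric Metric name, e.g. \code{"dR_whole"} or
#'   \code{"bg_freq_naive"}.
#' @return Data frame with \code{positivity}, \code{gamma_bar}, \code{mean},
#'   \code{sd}, \code{n}.
#' @export
sweep_metric <- function(sweep, metric) {
  stopifnot(inherits(sweep, "hgt_sweep"))
  st <- sweep$stats
  d <- st[st$metric == metric, c("positivity", "gamma_bar", "mean", "sd", "n")]
  if (nrow(d) == 0) stop("unknown metric: ", metric)
  rownames(d) <- NULL
  d
}

#' @export
print.hgt_sweep <- function(x, ...) {
  ng <- length(unique(x$cells$gamma_bar))
  np <- length(unique(x$cells$positivity))
  cat(sprintf("gLV-HGT sweep: %d mobility x %d positivity cells, %d communities/cell (seed %d)\n",
              ng, np, max(x$stats$n), x$seed))
  invisible(x)
}
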
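#' Read a run configuration from YAML
#'
#' The configuration mirrors the model parameter names (N, C, sigma, s,
#' positivity, c, gamma_bar, delta, beta_s, beta_r, D_perturb, D_prior,
#' t_adjust, t_perturb) under \code{params}, plus the experiment selector
#' and its grids. Unknown keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated \code{hgt_config} list with elements \code{params}
#'   (an \code{\link{hgt_params}}), \code{experiment}, \code{gamma_grid},
#'   \code{pm_grid}, \code{n_communities}, \code{seed}, \code{output_dir},
#'   \code{keep_trajectories}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

#' @rdname read_run_config
#' @param raw A list with the same structure as the YAML file.
#' @export
build_run_config <- function(raw) {
  top_known <- c("params", "experiment", "gamma_grid", "pm_grid",
                 "n_communities", "seed", "output_dir", "keep_trajectories")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  pr <- raw$params
  if (!is.null(pr)) {
    # YAML 1.1 readers turn a bare key "N" into the boolean FALSE; undo that
    names(pr)[names(pr) == "FALSE"] <- "N"
    # YAML uses the field name "c" for the gene cost, as in the model tables
    if ("c" %in% names(pr)) {
      pr$c_cost <- pr$c
      pr$c <- NULL
    }
    known <- names(formals(hgt_params))
    unknown <- setdiff(names(pr), known)
    if (length(unknown)) {
      stop("unknown config keys under params: ", paste(unknown, collapse = ", "))
    }
    params <- do.call(hgt_params, pr)
  } else {
    params <- hgt_params()
  }
  experiment <- raw$experiment %||% "single-quartet"
  if (!experiment %in% c("single-quartet", "mobility-sweep", "grid-sweep")) {
    stop("experiment must be one of single-quartet, mobility-sweep, grid-sweep")
  }
  cfg <- list(
    params = params,
    experiment = experiment,
    gamma_grid = as.numeric(raw$gamma_grid %||% 10^seq(-6, -2, length.out = 21)),
    pm_grid = as.numeric(raw$pm_grid %||% c(0, 0.5, 1)),
    n_communities = as.integer(raw$n_communities %||% 100L),
    seed = as.integer(raw$seed %||% 1L),
    output_dir = raw$output_dir %||% "results",
    keep_trajectories = isTRUE(raw$keep_trajectories)
  )
  if (cfg$n_communities < 1) stop("n_communities must be >= 1")
  if (any(cfg$gamma_grid < 0)) stop("gamma_grid entries must be nonnegative")
  if (any(cfg$pm_grid < 0 | cfg$pm_grid > 1)) stop("pm_grid must lie in [0, 1]")
  class(cfg) <- "hgt_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the experiment described by a configuration
#'
#' Executes the selected experiment (one quartet on one community, a
#' mobility sweep, or a positivity-by-mobility grid sweep), writes tidy CSV
#' results into the output directory, and writes a JSON manifest listing
#' every output file with an MD5 checksum alongside the seed and
#' configuration echo. Identical configuration and seed reproduce identical
#' result files.
#'
#' @param config An \code{hgt_config} (from \code{\link{read_run_config}})
#'   or a path to a YAML config.
#' @return Invisibly, a list with the computed result object and the
#'   manifest.
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "hgt_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (config$experiment == "single-quartet") {
    ens <- generate_ensemble(config$params, 1, config$seed)
    deltas <- community_deltas(ens[[1]], config$params)
    f <- file.path(config$output_dir, "quartet_deltas.csv")
    utils::write.csv(deltas, f, row.names = FALSE)
    files <- f
    result <- deltas
  } else {
    result <- if (config$experiment == "mobility-sweep") {
      sweep_mobility(config$params, config$gamma_grid, config$n_communities,
                     config$seed)
    } else {
      sweep_positivity_by_mobility(config$params, config$pm_grid,
                                   config$gamma_grid, config$n_communities,
                                   config$seed)
    }
    f1 <- file.path(config$output_dir, "sweep_cells.csv")
    f2 <- file.path(config$output_dir, "sweep_stats.csv")
    utils::write.csv(result$cells, f1, row.names = FALSE)
    utils::write.csv(result$stats, f2, row.names = FALSE)
    files <- c(f1, f2)
  }
  manifest <- list(
    experiment = config$experiment,
    seed = config$seed,
    n_communities = config$n_communities,
    package_version = as.character(utils::packageVersion("hgtstab")),
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  mf <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(result = result, manifest = manifest))
}

#' Serialize a community ensemble to JSON
#'
#' Matrices are written as nested arrays together with the seed metadata, so
#' an ensemble can be stored, shared, and reloaded exactly.
#'
#' @param ensemble An \code{hgt_ensemble}.
#' @param path Output JSON path.
#' @export
write_ensemble_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "hgt_ensemble"))
  payload <- list(
    seed = attr(ensemble, "seed"),
    communities = lapply(ensemble, function(cm) {
      list(A = cm$A, s_vec = cm$s_vec, r_vec = cm$r_vec, Z = cm$Z,
           gamma_bar = cm$gamma_bar, gamma_noise_rel = cm$gamma_noise_rel,
           mask = cm$mask, c = cm$c, focal = cm$focal, seed = cm$seed,
           id = cm$id)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cms <- payload$communities
  n <- length(cms$id)
  masks <- if ("mask" %in% names(cms)) cms[["mask"]] else NULL
  # absent masks come back as a zero-column data frame, present ones as a
  # list of matrices
  if (is.data.frame(masks) && ncol(masks) == 0) masks <- NULL
  # matrix fields simplify to either a list of matrices or a 3-d array
  get_mat <- function(col, i) {
    m <- if (is.list(col)) col[[i]] else col[i, , ]
    matrix(as.numeric(m), nrow = nrow(m))
  }
  get_vec <- function(col, i) {
    if (is.list(col)) as.numeric(col[[i]]) else as.numeric(col[i, ])
  }
  ens <- lapply(seq_len(n), function(i) {
    mask <- if (is.null(masks)) NULL else masks[[i]]
    if (length(mask) == 0) mask <- NULL
    if (!is.null(mask)) mask <- get_mat(masks, i)
    new_community(
      A = get_mat(cms$A, i),
      s_vec = get_vec(cms$s_vec, i), r_vec = get_vec(cms$r_vec, i),
      Z = get_mat(cms$Z, i),
      gamma_bar = cms$gamma_bar[i], gamma_noise_rel = cms$gamma_noise_rel[i],
      c_cost = cms$c[i], focal = cms$focal[i], seed = cms$seed[i],
      mask = mask,
      id = cms$id[i]
    )
  })
  class(ens) <- c("hgt_ensemble", "list")
  attr(ens, "seed") <- payload$seed
  ens
}

#' Mobility-sweep curves (mean with standard-deviation band)
#'
#' Plots the ensemble mean of a stability contrast at the three scopes
#' (whole community: solid; background: dashed; focal: dotted) against the
#' mean conjugation rate on a log axis, with a mean +/- sd ribbon.
#'
#' @param sweep An \code{hgt_sweep} with a single positivity value.
#' @param contrast \code{"dR"} or \code{"dE"}.
#' @return A ggplot object.
#' @export
plot_mobility_sweep <- function(sweep, contrast = c("dR", "dE")) {
  contrast <- match.arg(contrast)
  scopes <- paste0(contrast, c("_whole", "_background", "_focal"))
  d <- do.call(rbind, lapply(scopes, function(m) {
    x <- sweep_metric(sweep, m)
    x$scope <- sub(paste0(contrast, "_"), "", m)
    x
  }))
  if (length(unique(d$positivity)) > 1) {
    stop("sweep has multiple positivity values; use plot_grid_heatmap")
  }
  if (any(d$gamma_bar <= 0)) stop("log mobility axis requires gamma_bar > 0")
  d$scope <- factor(d$scope, levels = c("whole", "background", "focal"))
  ggplot2::ggplot(d, ggplot2::aes(x = gamma_bar, y = mean,
                                  linetype = scope)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd,
                                      ymax = mean + sd,
                                      group = scope),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean conjugation rate", y = contrast,
                  linetype = "scope") +
    ggplot2::theme_minimal()
}

#' Positivity-by-mobility heatmap of one metric's cell means
#'
#' @param sweep An \code{hgt_sweep} over both grids.
#' @param metric Metric name (e.g. \code{"dR_background"}).
#' @return A ggplot object with a diverging palette centred at 0.
#' @export
plot_grid_heatmap <- function(sweep, metric) {
  d <- sweep_metric(sweep, metric)
  if (nrow(d) == 0) stop("empty sweep")
  lim <- max(abs(d$mean))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(signif(gamma_bar, 3)),
                                  y = factor(positivity),
                                  fill = mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  limits = c(-lim, lim)) +
    ggplot2::labs(x = "mean conjugation rate", y = "positivity",
                  fill = metric) +
    ggplot2::theme_minimal()
}
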
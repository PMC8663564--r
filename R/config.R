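#' Read a YAML analysis configuration
#'
#' Supported keys (all optional): \code{column_map} (overrides for
#' \code{\link{default_column_map}} entries), \code{metric_map} (per-test
#' primary metric names), \code{cutoff_date} (\code{"YYYY-MM-DD"}),
#' \code{min_reps}, \code{min_weeks}, \code{time_axis}, \code{n_boot},
#' \code{tests}, and \code{sim} (arguments for \code{\link{sim_config}}).
#' Unspecified entries fall back to package defaults.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A list with fully populated configuration entries.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cm <- default_column_map()
  for (k in names(cfg$column_map)) cm[[k]] <- cfg$column_map[[k]]
  mm <- default_metric_map()
  for (k in names(cfg$metric_map)) mm[[k]] <- cfg$metric_map[[k]]
  list(
    column_map = cm,
    metric_map = mm,
    cutoff_date = cfg$cutoff_date,
    min_reps = if (is.null(cfg$min_reps)) 5 else cfg$min_reps,
    min_weeks = if (is.null(cfg$min_weeks)) 5 else cfg$min_weeks,
    time_axis = if (is.null(cfg$time_axis)) "repetition" else cfg$time_axis,
    n_boot = if (is.null(cfg$n_boot)) 1000 else cfg$n_boot,
    tests = cfg$tests,
    sim = cfg$sim
  )
}

#' Build a simulation configuration from a configuration list
#'
#' @param cfg A list as returned by \code{\link{load_config}} (its \code{sim}
#'   entry holds \code{\link{sim_config}} arguments).
#' @return A \code{\link{sim_config}}.
#' @export
sim_config_from_list <- function(cfg) {
  do.call(sim_config, if (is.null(cfg$sim)) list() else cfg$sim)
}
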
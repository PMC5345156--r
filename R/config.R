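#' Read a scenario or scenario-grid configuration file
#'
#' YAML configuration with scalar or list-valued scenario fields. Scalar
#' fields describe one scenario; any list-valued field among
#' `n_clusters`, `cell_size`, `icc`, `or_intervention`, `or_time` turns
#' the file into a factor grid (the Cartesian product of the supplied
#' levels). Recognised keys: `steps`, `n_clusters`, `cell_size`,
#' `baseline_mean`, `icc`, `or_intervention`, `or_time`, `replicates`,
#' `seed`, `methods`, `time_adjustment`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `grid` (data frame of scenario factors),
#'   `methods`, `time_adjustment` and `seed`, directly usable with
#'   [run_grid()].
#' @export
sw_read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(steps = 3L, n_clusters = 3L, cell_size = 100L,
                   baseline_mean = 0.1, icc = 0.01,
                   or_intervention = 2.25, or_time = 1,
                   replicates = 2000L, seed = 1L,
                   methods = c("glmm", "gee", "fixed_effects",
                               "cluster_summaries"),
                   time_adjustment = "linear")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  grid <- expand.grid(steps = as.integer(cfg$steps),
                      n_clusters = as.integer(unlist(cfg$n_clusters)),
                      cell_size = as.integer(unlist(cfg$cell_size)),
                      icc = as.numeric(unlist(cfg$icc)),
                      or_time = as.numeric(unlist(cfg$or_time)),
                      or_intervention = as.numeric(unlist(cfg$or_intervention)),
                      baseline_mean = as.numeric(cfg$baseline_mean),
                      KEEP.OUT.ATTRS = FALSE)
  grid$replicates <- as.integer(cfg$replicates)
  list(grid = grid,
       methods = as.character(unlist(cfg$methods)),
       time_adjustment = cfg$time_adjustment,
       seed = as.integer(cfg$seed))
}

#' Write grid results to CSV and JSON
#'
#' Writes the tidy scenario x method summary table as CSV and, next to
#' it, a JSON run log with the master seed, factor levels and totals of
#' discarded datasets and convergence failures.
#'
#' @param results Output of [run_grid()] (or [run_scenario()]).
#' @param csv_path Path of the CSV file. The JSON log is written to the
#'   same path with extension `.json` unless `json_path` is given.
#' @param json_path Optional explicit JSON path.
#' @return `csv_path`, invisibly.
#' @export
sw_write_results <- function(results, csv_path, json_path = NULL) {
  utils::write.csv(results, csv_path, row.names = FALSE)
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", csv_path)
  log <- list(
    master_seed = attr(results, "master_seed"),
    n_scenarios = if (!is.null(results$scenario_id))
      length(unique(results$scenario_id)) else 1L,
    methods = sort(unique(results$method)),
    total_replicates = sum(results$n_replicates[!duplicated(
      paste(results$scenario_id, results$seed))]),
    total_discarded_datasets = sum(results$n_discarded_datasets[!duplicated(
      paste(results$scenario_id, results$seed))]),
    total_convergence_failures = sum(results$n_replicates - results$n_converged),
    package_version = as.character(utils::packageVersion("stepwedgesim"))
  )
  jsonlite::write_json(log, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(csv_path)
}
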
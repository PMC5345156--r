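#' Per cent bias of a set of estimates
#'
#' `100 * (mean(estimates) - true_value) / true_value`.
#'
#' @param estimates Numeric vector of estimates (non-empty).
#' @param true_value True parameter value (non-zero).
#' @return Per cent bias.
#' @examples
#' percent_bias(c(0.07, 0.13, 0.10), 0.1)  # 0
#' @export
percent_bias <- function(estimates, true_value) {
  if (length(estimates) == 0) stop("'estimates' must be non-empty")
  if (!is.finite(true_value) || true_value == 0)
    stop("'true_value' must be a non-zero finite number")
  100 * (mean(estimates) - true_value) / true_value
}

#' Rejection rate of a set of p-values
#'
#' Fraction of p-values strictly below `alpha`: the type I error rate
#' when the simulated intervention effect is null, power otherwise.
#'
#' @param p_values Numeric vector in \[0, 1\] (non-empty).
#' @param alpha Significance level in (0, 1).
#' @return Proportion in \[0, 1\].
#' @examples
#' rejection_rate(c(0.03, 0.6, 0.04, 0.2), 0.05)  # 0.5
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("'p_values' must be non-empty")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1")
  mean(p_values < alpha)
}

#' Run all replicates of one scenario and summarise each method
#'
#' Generates `scenario$replicates` trial datasets (each from its own
#' random substream, with the no-events discard rule), fits every
#' requested method to every dataset, and aggregates the results into
#' one summary row per method: mean estimate, per cent bias against the
#' true effect, rejection rate at `alpha` (type I error under the null,
#' power otherwise) with its binomial Monte-Carlo standard error, the
#' mean standard error, and convergence accounting. Bias and rejection
#' summaries use converged fits only; failures are counted separately.
#'
#' Per cent bias for the GLMM, fixed effects and GEE methods is on the
#' log odds ratio scale against `log(or_intervention)` (the GEE estimate
#' is first converted to the cluster-specific scale, see
#' [marginal_to_conditional()]); for the cluster-summaries method it is
#' on the risk-difference scale against the scenario's `true_rd`. Under
#' a null intervention effect the true log odds ratio is zero, so per
#' cent bias is undefined and reported as `NA`.
#'
#' @param scenario An [sw_scenario()].
#' @param methods Character vector of methods (see [sw_fit()]).
#' @param time_adjustment Time adjustment applied to every method.
#' @param alpha Significance level for rejection.
#' @param conversion_icc Passed to the GEE fitter; default uses the
#'   scenario's design ICC.
#' @param keep_replicates Attach the per-replicate fit table as
#'   attribute `"replicates"` (useful for paired method comparisons).
#' @param ... Further arguments for the fitters (see [sw_fit()]); only
#'   meaningful when every requested method accepts them.
#' @return A data frame with one row per method, carrying the scenario
#'   factors and the summary columns described above. Deterministic
#'   given `scenario$seed`.
#' @examples
#' sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 50,
#'                   baseline_mean = 0.1, icc = 0.05,
#'                   or_intervention = 2.25, or_time = 1,
#'                   replicates = 20, seed = 42)
#' run_scenario(sc, methods = c("gee", "fixed_effects"))
#' @export
run_scenario <- function(scenario,
                         methods = c("glmm", "gee", "fixed_effects",
                                     "cluster_summaries"),
                         time_adjustment = "linear", alpha = 0.05,
                         conversion_icc = NULL, keep_replicates = FALSE,
                         ...) {
  stopifnot(inherits(scenario, "sw_scenario"), length(methods) >= 1)
  methods <- match.arg(methods, c("glmm", "gee", "fixed_effects",
                                  "cluster_summaries"), several.ok = TRUE)
  R <- scenario$replicates
  streams <- sw_streams(scenario$seed, R)
  rows <- vector("list", R * length(methods))
  n_discarded <- 0L
  for (r in seq_len(R)) {
    trial <- sw_simulate(scenario, stream = streams[[r]])
    n_discarded <- n_discarded + attr(trial, "n_discarded")
    for (mi in seq_along(methods)) {
      fit <- sw_fit(trial, methods[mi], time_adjustment = time_adjustment,
                    conversion_icc = conversion_icc, alpha = alpha, ...)
      row <- as.data.frame(fit)
      row$replicate <- r
      rows[[(r - 1L) * length(methods) + mi]] <- row
    }
  }
  reps <- do.call(rbind, rows)

  out <- do.call(rbind, lapply(methods, function(m) {
    sub <- reps[reps$method == m & reps$converged, , drop = FALSE]
    n_conv <- nrow(sub)
    if (m == "cluster_summaries") {
      truth <- scenario$true_rd
      est <- sub$estimate
    } else {
      truth <- scenario$beta1
      est <- if (m == "gee") sub$estimate_conditional else sub$estimate
    }
    rate <- if (n_conv > 0) rejection_rate(sub$p_value, alpha) else NA_real_
    data.frame(
      steps = scenario$steps, n_clusters = scenario$n_clusters,
      cell_size = scenario$cell_size, baseline_mean = scenario$baseline_mean,
      icc = scenario$icc, or_intervention = scenario$or_intervention,
      or_time = scenario$or_time, time_adjustment = time_adjustment,
      method = m, seed = scenario$seed,
      n_replicates = R, n_converged = n_conv,
      n_discarded_datasets = n_discarded,
      mean_estimate = if (n_conv > 0) mean(est) else NA_real_,
      percent_bias = if (n_conv > 0 && truth != 0) percent_bias(est, truth)
      else NA_real_,
      rejection_rate = rate,
      mc_se_rejection = if (n_conv > 0) sqrt(rate * (1 - rate) / n_conv)
      else NA_real_,
      mean_se = if (n_conv > 0) mean(sub$se) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' Factor grid of the three-step simulation study
#'
#' The full factorial over number of clusters \{3, 6, 9, 18, 36\}, cell
#' size \{5, 10, 50, 100\}, ICC \{0.01, 0.05, 0.1\}, time odds ratio
#' \{1, 1.227\} and intervention odds ratio \{1, 2.25\} at baseline mean
#' 0.1 with three steps: 240 scenarios.
#'
#' @param replicates Replicates per scenario.
#' @return Data frame of scenario factors, one row per scenario.
#' @export
scenario_a_grid <- function(replicates = 2000) {
  g <- expand.grid(steps = 3L,
                   n_clusters = c(3L, 6L, 9L, 18L, 36L),
                   cell_size = c(5L, 10L, 50L, 100L),
                   icc = c(0.01, 0.05, 0.1),
                   or_time = c(1, 1.227),
                   or_intervention = c(1, 2.25),
                   KEEP.OUT.ATTRS = FALSE)
  g$baseline_mean <- 0.1
  g$replicates <- as.integer(replicates)
  g
}

#' Factor grid of the six-step simulation study
#'
#' Six steps (seven measurement periods), clusters \{6, 12, 18, 36\},
#' cell sizes \{5, 10, 25, 50\}, baseline mean 0.2, weaker effects
#' (intervention OR \{1, 1.33\}, time OR \{1, 1.03\}), ICC
#' \{0.01, 0.05, 0.1\}: 192 scenarios.
#'
#' @param replicates Replicates per scenario.
#' @return Data frame of scenario factors, one row per scenario.
#' @export
scenario_b_grid <- function(replicates = 2000) {
  g <- expand.grid(steps = 6L,
                   n_clusters = c(6L, 12L, 18L, 36L),
                   cell_size = c(5L, 10L, 25L, 50L),
                   icc = c(0.01, 0.05, 0.1),
                   or_time = c(1, 1.03),
                   or_intervention = c(1, 1.33),
                   KEEP.OUT.ATTRS = FALSE)
  g$baseline_mean <- 0.2
  g$replicates <- as.integer(replicates)
  g
}

#' Run a grid of scenarios
#'
#' Executes [run_scenario()] over every row of a scenario-factor grid
#' (such as [scenario_a_grid()]) and binds the summaries into one tidy
#' table, one row per scenario x method. Each scenario receives a
#' deterministic seed derived from the master seed and its grid row, so
#' the full grid result is reproducible and invariant to execution
#' order.
#'
#' @param grid Data frame with columns `steps`, `n_clusters`,
#'   `cell_size`, `baseline_mean`, `icc`, `or_intervention`, `or_time`,
#'   `replicates` (missing `replicates` filled from the argument).
#' @param methods Methods fitted to every scenario.
#' @param time_adjustment Time adjustment applied throughout.
#' @param seed Master seed for the whole grid.
#' @param replicates Default replicates when the grid has no column.
#' @param alpha Significance level.
#' @param progress Print one line per completed scenario.
#' @return Data frame of scenario x method summaries with attributes
#'   `master_seed` and `grid`.
#' @examples
#' g <- scenario_a_grid(replicates = 5)[c(1, 21), ]
#' run_grid(g, methods = "gee", seed = 1)
#' @export
run_grid <- function(grid,
                     methods = c("glmm", "gee", "fixed_effects",
                                 "cluster_summaries"),
                     time_adjustment = "linear", seed = 1L,
                     replicates = NULL, alpha = 0.05, progress = FALSE) {
  if (nrow(grid) == 0) stop("empty scenario grid")
  if (!is.null(replicates)) grid$replicates <- as.integer(replicates)
  if (is.null(grid$replicates)) stop("no replicate count supplied")
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- sw_scenario(steps = grid$steps[i], n_clusters = grid$n_clusters[i],
                      cell_size = grid$cell_size[i],
                      baseline_mean = grid$baseline_mean[i],
                      icc = grid$icc[i],
                      or_intervention = grid$or_intervention[i],
                      or_time = grid$or_time[i],
                      replicates = grid$replicates[i],
                      seed = scenario_seed(seed, i))
    res[[i]] <- run_scenario(sc, methods = methods,
                             time_adjustment = time_adjustment, alpha = alpha)
    res[[i]]$scenario_id <- i
    if (progress)
      message(sprintf("scenario %d/%d done", i, nrow(grid)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "master_seed") <- seed
  attr(out, "grid") <- grid
  out
}

# Deterministic per-scenario seed below 2^31, spread out so that
# neighbouring scenarios do not share L'Ecuyer seeding states.
scenario_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + as.numeric(index) * 1000003) %%
               .Machine$integer.max)
}
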
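#' Specify one stepped wedge simulation scenario
#'
#' A scenario bundles the design (steps, clusters, cell size), the true
#' data-generating parameters (baseline mean, intra-cluster correlation,
#' intervention and time odds ratios), and the Monte-Carlo settings
#' (replicates, master seed) for a cross-sectional stepped wedge cluster
#' randomised trial with a binary outcome.
#'
#' The design has `steps` switch points and `steps + 1` measurement
#' periods: period 0 is all-control and at the final period every cluster
#' has crossed to intervention. Clusters must divide evenly into the
#' steps so that the same number of clusters switches at each step.
#'
#' @param steps Number of intervention switch points (>= 1).
#' @param n_clusters Total number of clusters M; must be divisible by
#'   `steps`.
#' @param cell_size Number of subjects measured per cluster per period
#'   (`n_jk`); the design is cross-sectional, so these are new subjects
#'   each period.
#' @param baseline_mean Mean true control-condition proportion, the mean
#'   of the beta distribution the cluster proportions are drawn from.
#' @param icc Intra-cluster correlation coefficient induced by the beta
#'   distribution, in (0, 1).
#' @param or_intervention True intervention effect odds ratio
#'   (cluster-specific scale). 1 means no effect.
#' @param or_time True odds ratio for one measurement period versus the
#'   previous one; the time trend is linear on the log-odds scale.
#' @param replicates Number of Monte-Carlo replicates when the scenario
#'   is run by [run_scenario()].
#' @param seed Master seed; each replicate receives its own independent
#'   random-number substream derived from it (see [sw_streams()]).
#'
#' @return An object of class `sw_scenario`: a list with the fields
#'   above plus `periods = steps + 1` and the implied true effects
#'   `beta1 = log(or_intervention)`, `beta2 = log(or_time)`, and
#'   `true_rd` (the true risk difference implied at the baseline mean,
#'   used as the truth for the cluster-summaries estimator).
#'
#' @examples
#' sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 50,
#'                   baseline_mean = 0.1, icc = 0.05,
#'                   or_intervention = 2.25, or_time = 1.227)
#' sc
#' @export
sw_scenario <- function(steps = 3, n_clusters = 3, cell_size = 100,
                        baseline_mean = 0.1, icc = 0.01,
                        or_intervention = 2.25, or_time = 1,
                        replicates = 2000, seed = 1L) {
  stopifnot(length(steps) == 1, length(n_clusters) == 1,
            length(cell_size) == 1)
  steps <- as.integer(steps)
  n_clusters <- as.integer(n_clusters)
  cell_size <- as.integer(cell_size)
  if (steps < 1L) stop("'steps' must be a positive integer")
  if (n_clusters < 1L) stop("'n_clusters' must be a positive integer")
  if (cell_size < 1L) stop("'cell_size' must be a positive integer")
  if (n_clusters %% steps != 0L)
    stop("'n_clusters' (", n_clusters, ") must be divisible by 'steps' (",
         steps, ") so that equal numbers of clusters switch at each step")
  if (!is.finite(baseline_mean) || baseline_mean <= 0 || baseline_mean >= 1)
    stop("'baseline_mean' must lie strictly between 0 and 1")
  if (!is.finite(icc) || icc <= 0 || icc >= 1)
    stop("'icc' must lie strictly between 0 and 1")
  if (!is.finite(or_intervention) || or_intervention <= 0)
    stop("'or_intervention' must be a positive number")
  if (!is.finite(or_time) || or_time <= 0)
    stop("'or_time' must be a positive number")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be a positive integer")

  beta1 <- log(or_intervention)
  structure(list(
    steps = steps,
    periods = steps + 1L,
    n_clusters = n_clusters,
    cell_size = cell_size,
    baseline_mean = baseline_mean,
    icc = icc,
    or_intervention = or_intervention,
    or_time = or_time,
    beta1 = beta1,
    beta2 = log(or_time),
    true_rd = stats::plogis(stats::qlogis(baseline_mean) + beta1) -
      baseline_mean,
    replicates = replicates,
    seed = as.integer(seed)
  ), class = "sw_scenario")
}

#' @export
print.sw_scenario <- function(x, ...) {
  cat("Stepped wedge scenario\n")
  cat(sprintf("  design    : %d steps, %d periods, %d clusters (%d per step), cell size %d\n",
              x$steps, x$periods, x$n_clusters, x$n_clusters %/% x$steps,
              x$cell_size))
  cat(sprintf("  truth     : baseline mean %.3g, ICC %.3g, intervention OR %.4g, time OR %.4g\n",
              x$baseline_mean, x$icc, x$or_intervention, x$or_time))
  cat(sprintf("  monte carlo: %d replicates, master seed %d\n",
              x$replicates, x$seed))
  invisible(x)
}

#' Calibrate beta-distribution shape parameters to a mean and ICC
#'
#' True cluster proportions are drawn from a Beta(a, b) distribution.
#' Matching its mean `a / (a + b)` to `mu` and the induced intra-cluster
#' correlation `1 / (a + b + 1)` to `rho` gives the closed-form solution
#' `a = mu * (1 / rho - 1)`, `b = (1 - mu) * (1 / rho - 1)`.
#'
#' @param mu Target mean proportion in (0, 1).
#' @param rho Target intra-cluster correlation in (0, 1).
#' @return A list with positive shape parameters `a` and `b`.
#' @examples
#' solve_beta_params(0.1, 0.01)  # a = 9.9, b = 89.1
#' @export
solve_beta_params <- function(mu, rho) {
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu) ||
      mu <= 0 || mu >= 1)
    stop("'mu' must lie strictly between 0 and 1")
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) ||
      rho <= 0 || rho >= 1)
    stop("'rho' must lie strictly between 0 and 1")
  s <- 1 / rho - 1          # a + b
  list(a = mu * s, b = (1 - mu) * s)
}

#' True probability of the event in one cluster-period cell
#'
#' Inverse-logit of the cell linear predictor
#' `beta0k + beta1 * x + beta2 * j`, where `beta0k` is the cluster's
#' baseline log-odds, `x` the treatment indicator, and `j` the period
#' index (0-based, so the time odds ratio applies per period).
#'
#' @param beta0k Cluster baseline log-odds (logit of the true baseline
#'   proportion). Vectorised.
#' @param x Treatment indicator, 0 or 1.
#' @param j Period index 0, 1, ....
#' @param beta1 Log odds ratio of the intervention effect.
#' @param beta2 Log odds ratio per unit of period.
#' @return Probability strictly in (0, 1).
#' @examples
#' cell_probability(qlogis(0.1), 1, 0, log(2.25), 0)  # 0.2
#' @export
cell_probability <- function(beta0k, x, j, beta1, beta2) {
  stopifnot(all(is.finite(beta0k)), all(is.finite(x)), all(is.finite(j)),
            is.finite(beta1), is.finite(beta2))
  stats::plogis(beta0k + beta1 * x + beta2 * j)
}
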
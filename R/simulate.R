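#' Randomise clusters to intervention switch times
#'
#' Clusters are permuted uniformly at random and chunked into `steps`
#' equal groups; group g crosses from control to intervention immediately
#' before measurement period g (periods are indexed 0..steps). Every
#' equal-sized partition of the clusters is equally likely.
#'
#' @param n_clusters Number of clusters, divisible by `steps`.
#' @param steps Number of switch points.
#' @return Integer vector of length `n_clusters`: the first intervention
#'   period (1..steps) for each cluster.
#' @examples
#' set.seed(1); allocate_steps(6, 3)
#' @export
allocate_steps <- function(n_clusters, steps) {
  n_clusters <- as.integer(n_clusters)
  steps <- as.integer(steps)
  if (n_clusters %% steps != 0L)
    stop("'n_clusters' must be divisible by 'steps'")
  per_step <- n_clusters %/% steps
  alloc <- integer(n_clusters)
  alloc[sample.int(n_clusters)] <- rep(seq_len(steps), each = per_step)
  alloc
}

#' Simulate one cross-sectional stepped wedge trial
#'
#' Generates a single trial realisation under the beta-binomial/logistic
#' mechanism: true baseline cluster proportions `p_0k ~ Beta(a, b)` with
#' `(a, b)` calibrated to the scenario's mean and ICC
#' ([solve_beta_params()]), cluster intercepts `beta_0k = logit(p_0k)`,
#' a uniformly random step allocation, cell probabilities from the
#' logistic model in treatment and period ([cell_probability()]), and
#' cell event counts as Binomial(cell_size, p_jk) — equivalent to that
#' many independent Bernoulli subjects, since subjects within a cell are
#' exchangeable.
#'
#' A realisation in which the control condition has no events at all, or
#' the intervention condition has no events at all, is discarded and
#' regenerated from a fresh random substream (such trials are
#' unanalysable by several of the candidate methods). Discards are rare
#' under non-degenerate settings; after `max_retries` discards the
#' scenario is considered degenerate and an error is raised.
#'
#' @param scenario An [sw_scenario()].
#' @param stream Optional L'Ecuyer-CMRG state vector (one element of
#'   [sw_streams()]). If `NULL`, the current RNG state is used.
#' @param max_retries Maximum number of discarded datasets before
#'   failing.
#' @return An object of class `sw_trial`: a data frame with one row per
#'   cluster-period cell and columns `cluster`, `period` (0-based),
#'   `treatment`, `n`, `events`, `p_true`, plus attributes `p0k`,
#'   `beta0k`, `step_allocation`, `n_discarded` and `scenario`.
#' @examples
#' sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 20,
#'                   baseline_mean = 0.1, icc = 0.05,
#'                   or_intervention = 2.25, or_time = 1.227)
#' tr <- sw_simulate(sc, stream = sw_streams(1, 1)[[1]])
#' head(tr)
#' @export
sw_simulate <- function(scenario, stream = NULL, max_retries = 1000L) {
  stopifnot(inherits(scenario, "sw_scenario"))
  if (is.null(stream)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    stream <- get(".Random.seed", envir = globalenv())
  }
  n_discarded <- 0L
  repeat {
    res <- with_stream(stream, sw_simulate_once(scenario))
    trial <- res$value
    ctrl <- trial$treatment == 0L
    if (sum(trial$events[ctrl]) > 0L && sum(trial$events[!ctrl]) > 0L) {
      attr(trial, "n_discarded") <- n_discarded
      return(trial)
    }
    n_discarded <- n_discarded + 1L
    if (n_discarded >= max_retries)
      stop("discarded ", n_discarded, " datasets in a row; the scenario ",
           "is degenerate (events are essentially impossible in one arm)")
    # a discarded dataset consumes its substream; regenerate from the next
    stream <- parallel::nextRNGSubStream(stream)
  }
}

# One draw of the generator, no discard rule. Uses the current RNG state.
sw_simulate_once <- function(scenario) {
  M <- scenario$n_clusters
  P <- scenario$periods
  ab <- solve_beta_params(scenario$baseline_mean, scenario$icc)
  p0k <- stats::rbeta(M, ab$a, ab$b)
  beta0k <- stats::qlogis(p0k)
  alloc <- allocate_steps(M, scenario$steps)

  cluster <- rep(seq_len(M), each = P)
  period <- rep(0:(P - 1L), times = M)
  treatment <- as.integer(period >= alloc[cluster])
  p_true <- cell_probability(beta0k[cluster], treatment, period,
                             scenario$beta1, scenario$beta2)
  n <- rep(scenario$cell_size, length(cluster))
  events <- stats::rbinom(length(cluster), n, p_true)

  trial <- data.frame(cluster = cluster, period = period,
                      treatment = treatment, n = n, events = events,
                      p_true = p_true)
  structure(trial,
            class = c("sw_trial", "data.frame"),
            p0k = p0k, beta0k = beta0k, step_allocation = alloc,
            n_discarded = 0L, scenario = scenario)
}

#' @export
print.sw_trial <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Simulated stepped wedge trial: %d clusters x %d periods, cell size %d (N = %d)\n",
              sc$n_clusters, sc$periods, sc$cell_size, sum(x$n)))
  cat(sprintf("  events: %d control, %d intervention; datasets discarded before this one: %d\n",
              sum(x$events[x$treatment == 0L]),
              sum(x$events[x$treatment == 1L]),
              attr(x, "n_discarded")))
  print.data.frame(utils::head(as.data.frame(x), 8L), ...)
  if (nrow(x) > 8L) cat("  ... ", nrow(x) - 8L, " more cells\n", sep = "")
  invisible(x)
}

#' Treatment indicator matrix of a trial
#'
#' @param trial An `sw_trial`.
#' @param sort_clusters Order rows by switch period, which displays the
#'   canonical lower-triangular stepped wedge pattern.
#' @return 0/1 matrix, clusters x periods.
#' @export
treatment_matrix <- function(trial, sort_clusters = TRUE) {
  sc <- attr(trial, "scenario")
  m <- matrix(trial$treatment, nrow = sc$n_clusters, ncol = sc$periods,
              byrow = TRUE,
              dimnames = list(cluster = seq_len(sc$n_clusters),
                              period = 0:(sc$periods - 1L)))
  if (sort_clusters) m <- m[order(attr(trial, "step_allocation")), , drop = FALSE]
  m
}

#' Plot observed cluster-period proportions of a simulated trial
#'
#' One line per cluster over periods; filled points mark intervention
#' cells, open points control cells.
#'
#' @param x An `sw_trial`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sw_trial <- function(x, ...) {
  sc <- attr(x, "scenario")
  prop <- matrix(x$events / x$n, nrow = sc$periods, ncol = sc$n_clusters)
  graphics::matplot(0:(sc$periods - 1L), prop, type = "l", lty = 1,
                    col = grDevices::grey(0.6),
                    xlab = "period", ylab = "observed proportion", ...)
  trt <- matrix(x$treatment, nrow = sc$periods, ncol = sc$n_clusters)
  graphics::matpoints(0:(sc$periods - 1L), prop, pch = ifelse(trt == 1, 16, 1),
                      col = 1)
  invisible(x)
}

#' Write a trial to CSV
#'
#' One row per cluster-period cell with columns cluster, period,
#' treatment, n, events, p_true, for external cross-checking.
#'
#' @param trial An `sw_trial`.
#' @param path Output file path.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}
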
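# Fixed-effects design matrix for a trial at cell level.
#
# Columns: intercept, treatment, then the time terms implied by
# `time_adjustment`: "linear" adds the period index as one column,
# "categorical" adds an indicator per period j > 0 (period 0 reference),
# "none" adds nothing. With `cluster_effects = TRUE`, indicators for
# clusters 2..M (cluster 1 reference) are appended.
sw_design_matrix <- function(trial, time_adjustment = "linear",
                             cluster_effects = FALSE) {
  time_adjustment <- match.arg(time_adjustment,
                               c("linear", "categorical", "none"))
  X <- cbind(`(Intercept)` = 1, treatment = trial$treatment)
  if (time_adjustment == "linear") {
    X <- cbind(X, period = trial$period)
  } else if (time_adjustment == "categorical") {
    periods <- sort(unique(trial$period))
    for (j in periods[-1L])
      X <- cbind(X, as.integer(trial$period == j))
    colnames(X)[seq(3L, length.out = length(periods) - 1L)] <-
      paste0("period", periods[-1L])
  }
  if (cluster_effects) {
    clusters <- sort(unique(trial$cluster))
    if (length(clusters) > 1L) {
      C <- matrix(0L, nrow(trial), length(clusters) - 1L,
                  dimnames = list(NULL, paste0("cluster", clusters[-1L])))
      for (idx in seq_along(clusters[-1L]))
        C[trial$cluster == clusters[-1L][idx], idx] <- 1L
      X <- cbind(X, C)
    }
  }
  X
}

# Cluster-indicator (random effect) design at cell level: one column per
# cluster.
sw_cluster_design <- function(trial) {
  clusters <- sort(unique(trial$cluster))
  Z <- matrix(0L, nrow(trial), length(clusters),
              dimnames = list(NULL, paste0("cluster", clusters)))
  for (idx in seq_along(clusters)) Z[trial$cluster == clusters[idx], idx] <- 1L
  Z
}

#' Containment degrees of freedom for cluster random-intercept models
#'
#' The containment approximation assigns, to a fixed effect that is not
#' contained in the cluster random effect (here treatment and time both
#' vary within clusters), `df = N - rank([X Z])`, where `X` is the
#' fixed-effects design, `Z` the cluster-indicator random-effects design
#' and `N` the number of modelled rows: individual subjects for the
#' logistic mixed model, cluster-period cells for the cluster-summaries
#' linear mixed model.
#'
#' @param trial An `sw_trial`.
#' @param method `"glmm"` (subject-level rows) or `"cluster_summaries"`
#'   (cell-level rows).
#' @param time_adjustment `"linear"`, `"categorical"` or `"none"`.
#' @return The degrees of freedom (positive number).
#' @examples
#' sc <- sw_scenario(steps = 3, n_clusters = 3, cell_size = 100,
#'                   baseline_mean = 0.1, icc = 0.05)
#' tr <- sw_simulate(sc, stream = sw_streams(1, 1)[[1]])
#' containment_df(tr, "glmm", "linear")              # 1200 - 5 = 1195
#' containment_df(tr, "cluster_summaries", "linear") # 12 - 5 = 7
#' @export
containment_df <- function(trial, method = c("glmm", "cluster_summaries"),
                           time_adjustment = "linear") {
  method <- match.arg(method)
  X <- sw_design_matrix(trial, time_adjustment)
  Z <- sw_cluster_design(trial)
  r <- qr(cbind(X, Z))$rank
  n_obs <- if (method == "glmm") sum(trial$n) else nrow(trial)
  df <- n_obs - r
  if (df <= 0)
    stop("containment degrees of freedom are non-positive; the design is ",
         "rank deficient beyond the usual intercept/cluster confounding")
  df
}

#' Two-sided Wald test p-value
#'
#' @param estimate Parameter estimate.
#' @param se Standard error (> 0).
#' @param reference Reference distribution: `"normal"`, `"t"` (requires
#'   `df`) or `"chisq1"` (the squared statistic against chi-squared with
#'   1 df; identical to `"normal"` for two-sided tests).
#' @param df Degrees of freedom when `reference = "t"`.
#' @return p-value in \[0, 1\].
#' @examples
#' wald_test(1.959964, 1, "normal")  # 0.05
#' @export
wald_test <- function(estimate, se, reference = c("normal", "t", "chisq1"),
                      df = NULL) {
  reference <- match.arg(reference)
  if (!is.finite(se) || se <= 0) stop("'se' must be a positive number")
  z <- estimate / se
  switch(reference,
         normal = 2 * stats::pnorm(-abs(z)),
         t = {
           if (is.null(df)) stop("'df' is required for the t reference")
           2 * stats::pt(-abs(z), df = df)
         },
         chisq1 = stats::pchisq(z^2, df = 1, lower.tail = FALSE))
}
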
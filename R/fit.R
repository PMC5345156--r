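#' Fit an intervention-effect estimator to a stepped wedge trial
#'
#' Front end to the four candidate analysis methods for a
#' cross-sectional stepped wedge trial with a binary outcome:
#'
#' * `"glmm"` — random-intercept logistic mixed model, marginal
#'   likelihood maximised with adaptive Gauss-Hermite quadrature
#'   (`nodes` points); Wald t test with containment degrees of freedom.
#'   Estimates a cluster-specific log odds ratio.
#' * `"gee"` — logistic generalised estimating equations with an
#'   exchangeable working correlation and robust (sandwich) variance;
#'   Wald test against the standard normal. Estimates a
#'   population-average log odds ratio; the cluster-specific scale
#'   conversion `beta1 / (1 - icc)` is reported alongside
#'   (see [marginal_to_conditional()]).
#' * `"fixed_effects"` — logistic regression with cluster indicator
#'   fixed effects; 1-df chi-squared Wald test. Log odds ratio.
#' * `"cluster_summaries"` — linear mixed model on cluster-period event
#'   proportions with a cluster random intercept, fitted by REML; Wald t
#'   test with containment degrees of freedom. Estimates a risk
#'   difference.
#'
#' @param trial An `sw_trial` from [sw_simulate()], or any data frame
#'   with columns `cluster`, `period`, `treatment`, `n`, `events`.
#' @param method One of `"glmm"`, `"gee"`, `"fixed_effects"`,
#'   `"cluster_summaries"`.
#' @param time_adjustment How the secular time trend enters the model:
#'   `"linear"` (period index as one covariate, the default),
#'   `"categorical"` (an indicator per period after the first) or
#'   `"none"` (no time terms; biased when a real trend exists).
#' @param conversion_icc ICC used for the GEE marginal-to-conditional
#'   conversion. Defaults to the design ICC carried by a simulated
#'   trial; set to `"estimated"` to use the fitted working correlation
#'   (for real data, where the true ICC is unknown).
#' @param nodes Quadrature nodes for the GLMM.
#' @param alpha Significance level recorded on the result.
#' @param ... Further arguments for the individual fitters, e.g.
#'   `se_type = "model"` to base the GEE test on the model-based
#'   (working covariance) standard error instead of the default robust
#'   sandwich.
#' @return An object of class `sw_fit`; see [sw_fit_result()] for its
#'   fields. Use `coef()`, `summary()` or `as.data.frame()` to extract
#'   results.
#' @examples
#' sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 100,
#'                   baseline_mean = 0.1, icc = 0.05,
#'                   or_intervention = 2.25, or_time = 1.227)
#' tr <- sw_simulate(sc, stream = sw_streams(7, 1)[[1]])
#' sw_fit(tr, "glmm")
#' @export
sw_fit <- function(trial, method = c("glmm", "gee", "fixed_effects",
                                     "cluster_summaries"),
                   time_adjustment = c("linear", "categorical", "none"),
                   conversion_icc = NULL, nodes = 4L, alpha = 0.05, ...) {
  method <- match.arg(method)
  time_adjustment <- match.arg(time_adjustment)
  required <- c("cluster", "period", "treatment", "n", "events")
  if (!all(required %in% names(trial)))
    stop("'trial' must have columns ", paste(required, collapse = ", "))
  switch(method,
         glmm = fit_glmm(trial, time_adjustment, nodes = nodes,
                         alpha = alpha, ...),
         gee = fit_gee(trial, time_adjustment,
                       conversion_icc = conversion_icc, alpha = alpha, ...),
         fixed_effects = fit_fixed_effects(trial, time_adjustment,
                                           alpha = alpha, ...),
         cluster_summaries = fit_cluster_lmm(trial, time_adjustment,
                                             alpha = alpha, ...))
}

#' Construct a fit result
#'
#' Container returned by [sw_fit()] and the individual fitters. Mostly
#' for internal use; documented because harness output maps directly to
#' these fields.
#'
#' @param method,time_adjustment Model identifiers.
#' @param estimate Intervention-effect estimate: log odds ratio
#'   (cluster-specific for glmm/fixed effects, population-average for
#'   gee) or risk difference (cluster summaries).
#' @param estimate_conditional GEE only: the cluster-specific conversion
#'   `estimate / (1 - icc)`.
#' @param se Standard error of `estimate`.
#' @param df Degrees of freedom of the reference t distribution
#'   (`Inf` for normal / chi-squared references).
#' @param p_value Two-sided Wald p-value.
#' @param converged Logical; `FALSE` results carry a `reason` and are
#'   excluded from harness summaries.
#' @param reason Diagnostic string for non-convergence.
#' @param coefficients Full fixed-effect coefficient vector.
#' @param sigma_u Random-intercept standard deviation, where estimated.
#' @param working_alpha GEE working correlation estimate.
#' @param loglik Maximised log-likelihood, where defined.
#' @param alpha Significance level recorded for convenience.
#' @param trial The fitted trial (stored as dimensions only).
#' @return An object of class `sw_fit`.
#' @keywords internal
#' @export
sw_fit_result <- function(method, time_adjustment,
                          estimate = NA_real_, estimate_conditional = NA_real_,
                          se = NA_real_, df = Inf, p_value = NA_real_,
                          converged = FALSE, reason = NA_character_,
                          coefficients = NULL, sigma_u = NA_real_,
                          working_alpha = NA_real_, loglik = NA_real_,
                          alpha = 0.05, trial = NULL) {
  structure(list(
    method = method,
    time_adjustment = time_adjustment,
    scale = if (method == "cluster_summaries") "risk-difference" else "log-odds",
    estimate = unname(estimate),
    estimate_conditional = unname(estimate_conditional),
    se = unname(se), df = unname(df), p_value = unname(p_value),
    converged = converged, reason = reason,
    coefficients = coefficients, sigma_u = unname(sigma_u),
    working_alpha = unname(working_alpha), loglik = unname(loglik),
    alpha = alpha,
    n_clusters = if (!is.null(trial)) length(unique(trial$cluster)) else NA_integer_,
    n_obs = if (!is.null(trial)) sum(trial$n) else NA_integer_
  ), class = "sw_fit")
}

method_label <- function(method) {
  c(glmm = "logistic GLMM (adaptive Gauss-Hermite)",
    gee = "logistic GEE (exchangeable, robust SE)",
    fixed_effects = "logistic regression with fixed cluster effects",
    cluster_summaries = "cluster-summaries linear mixed model")[[method]]
}

#' @export
print.sw_fit <- function(x, ...) {
  cat(method_label(x$method), "\n")
  cat("  time adjustment:", x$time_adjustment, "\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE:", x$reason, "\n")
    return(invisible(x))
  }
  ref <- if (is.finite(x$df)) sprintf("t(%g)", x$df)
  else if (x$method == "fixed_effects") "chi-squared(1)" else "normal"
  cat(sprintf("  intervention effect (%s): %.4f  SE %.4f  [%s]  p = %.4g\n",
              x$scale, x$estimate, x$se, ref, x$p_value))
  if (is.finite(x$estimate_conditional) && x$method == "gee")
    cat(sprintf("  cluster-specific conversion: %.4f\n", x$estimate_conditional))
  if (is.finite(x$sigma_u))
    cat(sprintf("  random-intercept SD: %.4f\n", x$sigma_u))
  if (is.finite(x$working_alpha))
    cat(sprintf("  working correlation: %.4f\n", x$working_alpha))
  invisible(x)
}

#' @export
summary.sw_fit <- function(object, ...) {
  print(object, ...)
  if (object$converged && !is.null(object$coefficients)) {
    cat("  coefficients:\n")
    print(round(object$coefficients, 4))
  }
  invisible(object)
}

#' @export
coef.sw_fit <- function(object, ...) {
  if (is.null(object$coefficients)) c(treatment = object$estimate)
  else object$coefficients
}

#' Flatten a fit to a one-row data frame
#'
#' @param x An `sw_fit`.
#' @param row.names,optional,... Ignored (data frame method signature).
#' @return One-row data frame with columns `method`, `time_adjustment`,
#'   `scale`, `estimate`, `estimate_conditional`, `se`, `df`, `p_value`,
#'   `converged`, `sigma_u`, `working_alpha`.
#' @export
as.data.frame.sw_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(method = x$method, time_adjustment = x$time_adjustment,
             scale = x$scale, estimate = x$estimate,
             estimate_conditional = x$estimate_conditional,
             se = x$se, df = x$df, p_value = x$p_value,
             converged = x$converged, sigma_u = x$sigma_u,
             working_alpha = x$working_alpha,
             stringsAsFactors = FALSE)
}

#' Convert a population-average log odds ratio to the cluster-specific scale
#'
#' For binary outcomes with cluster-correlated data, the marginal
#' (population-average) log odds ratio estimated by a GEE is attenuated
#' relative to the cluster-specific one estimated by a random-intercept
#' model by a factor of approximately `1 - icc`; this applies the
#' inverse inflation `beta1 / (1 - icc)`.
#'
#' @param beta1_marginal Marginal log odds ratio.
#' @param icc Intra-cluster correlation in \[0, 1).
#' @return Cluster-specific scale log odds ratio.
#' @examples
#' marginal_to_conditional(0.8109, 0.1)
#' @export
marginal_to_conditional <- function(beta1_marginal, icc) {
  if (!is.numeric(icc) || any(!is.finite(icc)) || any(icc < 0) || any(icc >= 1))
    stop("'icc' must lie in [0, 1)")
  beta1_marginal / (1 - icc)
}
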
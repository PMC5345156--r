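# Logistic regression with fixed cluster effects (indicators for
# clusters 2..M), fitted by iteratively reweighted least squares via
# stats::glm on the aggregated binomial counts. The intervention effect
# is tested with a 1-df chi-squared Wald statistic.
#
# Separation handling: a very large treatment coefficient means the
# estimate of interest itself is diverging and the fit is reported as
# failed. A cluster with no events at all only sends its own nuisance
# indicator to -infinity; its IRLS weights vanish and the treatment
# inference is unaffected, so such fits are kept (with many clusters
# this occurs regularly and is harmless; with 3 clusters losing a third
# of the data usually drags the treatment coefficient along, which the
# rule then catches).

fit_fixed_effects <- function(trial, time_adjustment = "linear",
                              alpha = 0.05, separation_limit = 15) {
  X <- sw_design_matrix(trial, time_adjustment, cluster_effects = TRUE)
  fail <- function(reason)
    sw_fit_result(method = "fixed_effects", time_adjustment = time_adjustment,
                  converged = FALSE, reason = reason, trial = trial)

  fit <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X, cbind(trial$events, trial$n - trial$events),
                     family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10, maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("IRLS error"))
  if (!fit$converged) return(fail("IRLS did not converge"))
  coefs <- fit$coefficients
  if (any(is.na(coefs))) return(fail("non-identifiable design"))
  if (abs(coefs[["treatment"]]) > separation_limit)
    return(fail("separation (treatment coefficient diverged)"))

  mu <- fit$fitted.values
  W <- trial$n * mu * (1 - mu)
  info <- crossprod(X, W * X)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0))
    return(fail("singular information"))
  se1 <- sqrt(cov[2, 2])
  est1 <- coefs[["treatment"]]
  sw_fit_result(
    method = "fixed_effects", time_adjustment = time_adjustment,
    estimate = est1, se = se1, df = Inf,
    p_value = wald_test(est1, se1, "chisq1"),
    converged = TRUE, coefficients = coefs,
    loglik = -fit$deviance / 2 + sum(lchoose(trial$n, trial$events)) +
      sum(ifelse(trial$events > 0, trial$events * log(trial$events / trial$n), 0) +
            ifelse(trial$n - trial$events > 0,
                   (trial$n - trial$events) * log(1 - trial$events / trial$n), 0)),
    alpha = alpha, trial = trial)
}
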
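# Cluster-summaries method: the event proportion pi_jk = events / n of
# every cluster-period cell is modelled by a linear mixed model with a
# cluster random intercept,
#   pi_jk = x_jk' beta + u_k + e_jk,  u_k ~ N(0, sigma_u^2), e ~ N(0, sigma_e^2),
# fitted by REML. The variance ratio lambda = sigma_u^2 / sigma_e^2 is
# profiled out: for fixed lambda, V* = I + lambda Z Z' gives closed-form
# GLS estimates, and the scalar REML criterion is optimised over
# log(lambda). The intervention effect is a risk difference, tested with
# a Wald t test on containment degrees of freedom. Cells enter
# unweighted (one row each), as in the model's definition.

fit_cluster_lmm <- function(trial, time_adjustment = "linear", alpha = 0.05,
                            log_lambda_range = c(-15, 15)) {
  X <- sw_design_matrix(trial, time_adjustment)
  Z <- sw_cluster_design(trial)
  y <- trial$events / trial$n
  n <- nrow(X)
  p <- ncol(X)
  ZZt <- tcrossprod(Z)

  fail <- function(reason)
    sw_fit_result(method = "cluster_summaries",
                  time_adjustment = time_adjustment,
                  converged = FALSE, reason = reason, trial = trial)

  prof <- function(log_lambda) {
    lambda <- exp(log_lambda)
    Vs <- diag(n) + lambda * ZZt
    R <- tryCatch(chol(Vs), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdet_V <- 2 * sum(log(diag(R)))
    Xw <- backsolve(R, X, transpose = TRUE)
    yw <- backsolve(R, y, transpose = TRUE)
    XtVX <- crossprod(Xw)
    ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch2)) return(NULL)
    beta <- backsolve(ch2, backsolve(ch2, crossprod(Xw, yw), transpose = TRUE))
    resid <- yw - Xw %*% beta
    q <- sum(resid^2)                       # r' V*^-1 r
    sigma2 <- q / (n - p)
    logdet_XtVX <- 2 * sum(log(diag(ch2)))
    reml_ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(max(sigma2, 1e-300)) +
                         logdet_V + logdet_XtVX + (n - p))
    list(reml_ll = reml_ll, beta = drop(beta), sigma2_e = sigma2,
         lambda = lambda, XtVX = XtVX)
  }

  obj <- function(ll) {
    f <- prof(ll)
    if (is.null(f)) return(1e10)
    -f$reml_ll
  }
  opt <- tryCatch(
    stats::optimize(obj, interval = log_lambda_range, tol = 1e-9),
    error = function(e) NULL)
  if (is.null(opt)) return(fail("REML optimisation failed"))
  # boundary at the lower end means sigma_u ~ 0; refit there exactly
  log_lambda <- if (opt$minimum < log_lambda_range[1] + 1e-3) -Inf
  else opt$minimum
  f <- if (is.finite(log_lambda)) prof(log_lambda) else {
    fit0 <- prof(log_lambda_range[1])     # lambda ~ 0: effectively OLS
    fit0$lambda <- 0
    fit0
  }
  if (is.null(f)) return(fail("non-positive-definite profiled covariance"))

  cov_beta <- tryCatch(f$sigma2_e * solve(f$XtVX), error = function(e) NULL)
  if (is.null(cov_beta)) return(fail("singular GLS information"))
  est1 <- f$beta[2]
  se1 <- sqrt(cov_beta[2, 2])
  df <- containment_df(trial, "cluster_summaries", time_adjustment)
  p_value <- if (is.finite(se1) && se1 > 0) wald_test(est1, se1, "t", df = df)
  else NA_real_
  coefs <- f$beta
  names(coefs) <- colnames(X)
  sw_fit_result(
    method = "cluster_summaries", time_adjustment = time_adjustment,
    estimate = est1, se = se1, df = df, p_value = p_value,
    converged = TRUE, coefficients = coefs,
    sigma_u = sqrt(f$lambda * f$sigma2_e), loglik = f$reml_ll,
    alpha = alpha, trial = trial)
}

#' REML log-likelihood of the cluster-summaries linear mixed model
#'
#' Evaluates the restricted log-likelihood of the cell-proportion linear
#' mixed model at a given variance ratio, mainly for verification
#' against general-purpose mixed-model software.
#'
#' @param trial An `sw_trial` or compatible data frame.
#' @param lambda Variance ratio `sigma_u^2 / sigma_e^2` (>= 0).
#' @param time_adjustment `"linear"`, `"categorical"` or `"none"`.
#' @return Scalar REML log-likelihood (profiled over `beta` and
#'   `sigma_e^2`).
#' @export
sw_lmm_reml_loglik <- function(trial, lambda, time_adjustment = "linear") {
  X <- sw_design_matrix(trial, time_adjustment)
  Z <- sw_cluster_design(trial)
  y <- trial$events / trial$n
  n <- nrow(X); p <- ncol(X)
  Vs <- diag(n) + lambda * tcrossprod(Z)
  R <- chol(Vs)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  XtVX <- crossprod(Xw)
  beta <- solve(XtVX, crossprod(Xw, yw))
  q <- sum((yw - Xw %*% beta)^2)
  sigma2 <- q / (n - p)
  -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) +
            2 * sum(log(diag(R))) + determinant(XtVX)$modulus[1] + (n - p))
}
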
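# Random-intercept logistic mixed model fitted by maximising the
# marginal likelihood, with each cluster's one-dimensional random-effect
# integral approximated by adaptive (mode- and curvature-centred)
# Gauss-Hermite quadrature.

# Gauss-Hermite nodes and weights (physicists' convention:
# integral of exp(-x^2) f(x) dx = sum w_i f(x_i)), via the Golub-Welsch
# eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x < 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

# Internal workspace shared by likelihood evaluations of one fit: the
# trial reshaped to periods x clusters matrices plus the fixed design.
glmm_data <- function(trial, time_adjustment) {
  X <- sw_design_matrix(trial, time_adjustment)
  P <- length(unique(trial$period))
  M <- length(unique(trial$cluster))
  list(X = X,
       Y = matrix(trial$events, nrow = P, ncol = M),
       N = matrix(trial$n, nrow = P, ncol = M),
       P = P, M = M,
       lconst = sum(lchoose(trial$n, trial$events)))
}

# Per-cluster unnormalised log posterior of the random intercept u
# (binomial log-likelihood plus Normal(0, sigma^2) log-density), for a
# vector u of length M. ETA is the P x M matrix of fixed-effect linear
# predictors.
glmm_h <- function(u, ETA, d, sigma2) {
  ETAu <- ETA + rep(u, each = d$P)
  colSums(d$Y * ETAu - d$N * log1pexp(ETAu)) -
    u^2 / (2 * sigma2) - 0.5 * log(2 * pi * sigma2)
}

# Marginal log-likelihood by adaptive GHQ. `beta` are the fixed effects
# (matching columns of d$X), `sigma` the random-intercept SD.
glmm_marginal_loglik <- function(beta, sigma, d, gh, u_start = NULL) {
  sigma2 <- max(sigma^2, 1e-300)
  ETA <- matrix(d$X %*% beta, nrow = d$P, ncol = d$M)
  u <- if (is.null(u_start)) numeric(d$M) else u_start
  h <- glmm_h(u, ETA, d, sigma2)
  # damped Newton for the per-cluster posterior modes (h is strictly
  # concave in u, so this is globally convergent)
  for (iter in 1:50) {
    ETAu <- ETA + rep(u, each = d$P)
    p <- stats::plogis(ETAu)
    g <- colSums(d$Y - d$N * p) - u / sigma2
    Hneg <- colSums(d$N * p * (1 - p)) + 1 / sigma2
    step <- g / Hneg
    repeat {
      h_new <- glmm_h(u + step, ETA, d, sigma2)
      if (all(h_new >= h - 1e-12) || max(abs(step)) < 1e-14) break
      step <- step / 2
    }
    u <- u + step
    h <- h_new
    if (max(abs(g / Hneg)) < 1e-10) break
  }
  ETAu <- ETA + rep(u, each = d$P)
  p <- stats::plogis(ETAu)
  tau <- 1 / sqrt(colSums(d$N * p * (1 - p)) + 1 / sigma2)
  # log integral_k = log(sqrt(2) tau_k) + lse_q [log w_q + z_q^2 + h_k(u_k + sqrt(2) tau_k z_q)]
  Q <- length(gh$nodes)
  idx <- rep(seq_len(d$M), Q)
  U <- outer(sqrt(2) * tau, gh$nodes) + u       # M x Q node locations
  ETAq <- ETA[, idx, drop = FALSE] + rep(U, each = d$P)
  hq <- colSums(d$Y[, idx, drop = FALSE] * ETAq -
                  d$N[, idx, drop = FALSE] * log1pexp(ETAq)) -
    as.vector(U)^2 / (2 * sigma2) - 0.5 * log(2 * pi * sigma2)
  A <- matrix(hq + rep(log(gh$weights) + gh$nodes^2, each = d$M), d$M, Q)
  amax <- apply(A, 1, max)
  ll <- sum(log(sqrt(2) * tau) + amax + log(rowSums(exp(A - amax)))) + d$lconst
  attr(ll, "u_hat") <- u
  ll
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates the marginal log-likelihood (including binomial constants)
#' of the logistic mixed model
#' `logit p_jk = X beta + u_k`, `u_k ~ Normal(0, sigma^2)`, with each
#' cluster's random-effect integral approximated by adaptive
#' Gauss-Hermite quadrature centred and scaled at the cluster's
#' posterior mode.
#'
#' @param trial An `sw_trial` (or data frame with columns `cluster`,
#'   `period`, `treatment`, `n`, `events`).
#' @param beta Fixed-effect vector matching the design implied by
#'   `time_adjustment` (intercept, treatment, time terms).
#' @param sigma Random-intercept standard deviation (>= 0).
#' @param time_adjustment `"linear"`, `"categorical"` or `"none"`.
#' @param nodes Number of quadrature nodes.
#' @return The log-likelihood (a scalar).
#' @export
sw_glmm_loglik <- function(trial, beta, sigma, time_adjustment = "linear",
                           nodes = 4L) {
  d <- glmm_data(trial, time_adjustment)
  gh <- gauss_hermite(nodes)
  as.numeric(glmm_marginal_loglik(beta, sigma, d, gh))
}

# GLMM fitter. Optimises (beta, log sigma) by BFGS from a pooled-GLM
# start; sigma is profiled on the log scale to enforce positivity, and a
# boundary solution (log sigma < -8) is treated as a converged sigma = 0
# fit, with fixed effects then equal to the pooled logistic fit.
fit_glmm <- function(trial, time_adjustment = "linear", nodes = 4L,
                     alpha = 0.05) {
  d <- glmm_data(trial, time_adjustment)
  gh <- gauss_hermite(nodes)
  p <- ncol(d$X)

  glm0 <- tryCatch(
    suppressWarnings(
      stats::glm.fit(d$X, cbind(trial$events, trial$n - trial$events),
                     family = stats::binomial())),
    error = function(e) NULL)
  beta0 <- if (!is.null(glm0) && all(is.finite(glm0$coefficients)))
    glm0$coefficients else rep(0, p)

  env <- new.env()
  env$u <- numeric(d$M)
  negll <- function(par) {
    ll <- glmm_marginal_loglik(par[seq_len(p)], exp(par[p + 1L]), d, gh,
                               u_start = env$u)
    env$u <- attr(ll, "u_hat")
    v <- -as.numeric(ll)
    if (!is.finite(v)) return(1e10)
    v
  }

  fail <- function(reason) {
    sw_fit_result(method = "glmm", time_adjustment = time_adjustment,
                  converged = FALSE, reason = reason, trial = trial)
  }
  # log sigma is bounded below so that a variance-component estimate
  # collapsing to zero terminates cleanly at the boundary instead of
  # drifting along the flat profile
  opt <- tryCatch(
    stats::optim(c(beta0, log(0.3)), negll, method = "L-BFGS-B",
                 lower = c(rep(-Inf, p), -10), upper = c(rep(Inf, p), 5),
                 control = list(maxit = 200, factr = 4.5e7)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0)
    return(fail(if (is.null(opt)) "optimiser error" else "optimiser did not converge"))

  df <- containment_df(trial, "glmm", time_adjustment)
  coefs <- opt$par[seq_len(p)]
  names(coefs) <- colnames(d$X)
  log_sigma <- opt$par[p + 1L]

  if (log_sigma < -8) {
    # boundary: variance component estimated as zero; the marginal model
    # collapses to the pooled logistic fit
    if (is.null(glm0) || !glm0$converged) return(fail("boundary fit, pooled GLM failed"))
    mu <- glm0$fitted.values
    W <- trial$n * mu * (1 - mu)
    cov_beta <- tryCatch(solve(crossprod(d$X, W * d$X)),
                         error = function(e) NULL)
    if (is.null(cov_beta) || any(diag(cov_beta) <= 0))
      return(fail("singular information at boundary"))
    est <- glm0$coefficients
    se <- sqrt(diag(cov_beta))
    return(sw_fit_result(
      method = "glmm", time_adjustment = time_adjustment,
      estimate = est[["treatment"]], se = se[[2]], df = df,
      p_value = wald_test(est[["treatment"]], se[[2]], "t", df = df),
      converged = TRUE, coefficients = est, sigma_u = 0,
      loglik = -opt$value, alpha = alpha, trial = trial))
  }

  H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
  cov <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov)[seq_len(p)] <= 0))
    return(fail("singular observed information"))

  se1 <- sqrt(cov[2, 2])
  est1 <- coefs[["treatment"]]
  sw_fit_result(
    method = "glmm", time_adjustment = time_adjustment,
    estimate = est1, se = se1, df = df,
    p_value = wald_test(est1, se1, "t", df = df),
    converged = TRUE, coefficients = coefs, sigma_u = exp(log_sigma),
    loglik = -opt$value, alpha = alpha, trial = trial)
}
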
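# Logistic GEE with an exchangeable working correlation among all
# subjects of a cluster (across periods) and the robust sandwich
# variance. Subjects within a cluster-period cell share a covariate row,
# so every quantity in the estimating equations reduces exactly to
# cell-level sums; the fitter below works on those closed-form
# reductions rather than expanding to individual Bernoulli records.
#
# With exchangeable correlation alpha, a cluster's working covariance is
# V = A^(1/2) [(1 - alpha) I + alpha 11'] A^(1/2), whose inverse by the
# Sherman-Morrison identity gives, per cluster k of size n_k:
#   c_k = alpha / ((1 - alpha) (1 - alpha + alpha n_k))
#   quasi-score   g_k = sum_j x_j [ r_j / (1 - alpha) - n_j sqrt(v_j) c_k E_k ]
#   bread   B_k = (1 - alpha)^-1 sum_j n_j v_j x_j x_j' - c_k s_k s_k'
# where r_j = S_j - n_j mu_j (cell residual total), v_j = mu_j (1 - mu_j),
# E_k = sum_j r_j / sqrt(v_j) (cluster sum of Pearson residuals) and
# s_k = sum_j n_j sqrt(v_j) x_j.

# `se_type` selects the variance estimator behind the reported standard
# error and p-value: "robust" is the Liang-Zeger sandwich, "model" the
# working-covariance (model-based) estimate phi * B^-1. Both are always
# computed and stored on the result (`se_robust`, `se_model`). The
# sandwich is the default; note that with very few clusters it is
# severely biased downward, so sandwich-based tests are strongly
# anti-conservative there.
fit_gee <- function(trial, time_adjustment = "linear",
                    conversion_icc = NULL, alpha = 0.05,
                    se_type = c("robust", "model"),
                    fixed_alpha = NULL, max_iter = 100L, tol = 1e-8) {
  se_type <- match.arg(se_type)
  X <- sw_design_matrix(trial, time_adjustment)
  p <- ncol(X)
  S <- trial$events
  n <- trial$n
  cl <- trial$cluster
  clusters <- sort(unique(cl))
  n_k <- as.numeric(tapply(n, cl, sum)[as.character(clusters)])
  pair_denom <- sum(n_k * (n_k - 1)) / 2 - p
  N <- sum(n)

  fail <- function(reason)
    sw_fit_result(method = "gee", time_adjustment = time_adjustment,
                  converged = FALSE, reason = reason, trial = trial)

  glm0 <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X, cbind(S, n - S), family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(glm0) || any(!is.finite(glm0$coefficients)))
    return(fail("initial logistic fit failed"))
  beta <- glm0$coefficients

  wc_alpha <- if (is.null(fixed_alpha)) 0 else fixed_alpha
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    if (any(v < 1e-12)) return(fail("fitted probabilities at the boundary"))
    r <- S - n * mu
    pearson <- r / sqrt(v)                       # cell sums of e_i
    # within-cell sums of squared subject residuals: y in {0,1}
    e2_cell <- (S * (1 - mu)^2 + (n - S) * mu^2) / v
    E_k <- as.numeric(tapply(pearson, cl, sum)[as.character(clusters)])
    e2_k <- as.numeric(tapply(e2_cell, cl, sum)[as.character(clusters)])
    phi <- sum(e2_k) / (N - p)
    if (is.null(fixed_alpha)) {
      # moment estimator over all within-cluster subject pairs
      wc_alpha <- sum((E_k^2 - e2_k) / 2) / (phi * pair_denom)
      lower <- -1 / (max(n_k) - 1)
      if (!is.finite(wc_alpha) || wc_alpha <= lower || wc_alpha >= 1)
        return(fail(sprintf(
          "working correlation %.3g outside (%.3g, 1)", wc_alpha, lower)))
    }
    c_k <- wc_alpha / ((1 - wc_alpha) * (1 - wc_alpha + wc_alpha * n_k))

    cs <- c_k[match(cl, clusters)]
    Ecl <- E_k[match(cl, clusters)]
    w_cell <- n * v / (1 - wc_alpha)
    B <- crossprod(X, w_cell * X)
    Sx <- rowsum((n * sqrt(v)) * X, cl)          # s_k rows, cluster order
    B <- B - crossprod(Sx, c_k * Sx)
    g_cell <- X * (r / (1 - wc_alpha) - n * sqrt(v) * cs * Ecl)
    G <- rowsum(g_cell, cl)                      # g_k rows
    score <- colSums(G)
    step <- tryCatch(solve(B, score), error = function(e) NULL)
    if (is.null(step)) return(fail("singular bread matrix"))
    beta <- beta + step
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) return(fail("quasi-score iterations did not converge"))

  # sandwich at the solution
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  v <- mu * (1 - mu)
  r <- S - n * mu
  pearson <- r / sqrt(v)
  E_k <- as.numeric(tapply(pearson, cl, sum)[as.character(clusters)])
  c_k <- wc_alpha / ((1 - wc_alpha) * (1 - wc_alpha + wc_alpha * n_k))
  cs <- c_k[match(cl, clusters)]
  Ecl <- E_k[match(cl, clusters)]
  w_cell <- n * v / (1 - wc_alpha)
  B <- crossprod(X, w_cell * X)
  Sx <- rowsum((n * sqrt(v)) * X, cl)
  B <- B - crossprod(Sx, c_k * Sx)
  G <- rowsum(X * (r / (1 - wc_alpha) - n * sqrt(v) * cs * Ecl), cl)
  Binv <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Binv)) return(fail("singular bread matrix"))
  e2_cell <- (S * (1 - mu)^2 + (n - S) * mu^2) / v
  phi <- sum(e2_cell) / (N - p)
  V <- Binv %*% crossprod(G) %*% Binv
  se_robust <- sqrt(V[2, 2])
  se_model <- sqrt(phi * Binv[2, 2])
  se1 <- if (se_type == "robust") se_robust else se_model
  if (!is.finite(se1) || se1 <= 0) return(fail("degenerate variance estimate"))
  est1 <- beta[["treatment"]]

  icc_used <- if (identical(conversion_icc, "estimated")) max(wc_alpha, 0)
  else if (is.numeric(conversion_icc)) conversion_icc
  else {
    sc <- attr(trial, "scenario")
    if (!is.null(sc)) sc$icc else 0
  }

  out <- sw_fit_result(
    method = "gee", time_adjustment = time_adjustment,
    estimate = est1,
    estimate_conditional = marginal_to_conditional(est1, icc_used),
    se = se1, df = Inf,
    p_value = wald_test(est1, se1, "normal"),
    converged = TRUE, coefficients = beta,
    working_alpha = wc_alpha, alpha = alpha, trial = trial)
  out$se_type <- se_type
  out$se_robust <- se_robust
  out$se_model <- se_model
  out
}
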
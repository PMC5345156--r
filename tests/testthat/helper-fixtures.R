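# Shared fixture builders. Everything is generated in code; no stored data.

# A small simulated trial under the default three-step design.
small_trial <- function(n_clusters = 3, cell_size = 10, icc = 0.05,
                        or_intervention = 2.25, or_time = 1.227,
                        baseline_mean = 0.1, steps = 3, seed = 1) {
  sc <- sw_scenario(steps = steps, n_clusters = n_clusters,
                    cell_size = cell_size, baseline_mean = baseline_mean,
                    icc = icc, or_intervention = or_intervention,
                    or_time = or_time, replicates = 1, seed = seed)
  sw_simulate(sc, stream = sw_streams(seed, 1)[[1]])
}

# A hand-built cluster-period table (bypasses the generator), for
# degenerate and closed-form cases. Columns follow the sw_trial contract.
manual_trial <- function(cluster, period, treatment, n, events) {
  data.frame(cluster = cluster, period = period, treatment = treatment,
             n = n, events = events,
             p_true = (events + 0.5) / (n + 1))
}

# Brute-force marginal log-likelihood of the random-intercept logistic
# model by one-dimensional quadrature of each cluster's integrand with
# stats::integrate (machine-precision oracle, independent of the
# adaptive Gauss-Hermite code path).
brute_force_glmm_loglik <- function(trial, beta, sigma,
                                    time_adjustment = "linear") {
  X <- stepwedgesim:::sw_design_matrix(trial, time_adjustment)
  eta <- drop(X %*% beta)
  ll <- sum(lchoose(trial$n, trial$events))
  for (k in unique(trial$cluster)) {
    idx <- trial$cluster == k
    integrand <- function(u) {
      vapply(u, function(ui) {
        exp(sum(stats::dbinom(trial$events[idx], trial$n[idx],
                              stats::plogis(eta[idx] + ui), log = TRUE)) -
              sum(lchoose(trial$n[idx], trial$events[idx]))) *
          stats::dnorm(ui, 0, sigma)
      }, numeric(1))
    }
    ll <- ll + log(stats::integrate(integrand, -Inf, Inf,
                                    rel.tol = 1e-12)$value)
  }
  ll
}

# Explicit subject-level GEE matrices (bread, meat, sandwich) for an
# exchangeable working correlation, built by brute-force expansion of
# every cell into individual Bernoulli rows. Independent of the
# closed-form cell reductions used by the fitter.
brute_force_gee_sandwich <- function(trial, beta, wc_alpha,
                                     time_adjustment = "linear") {
  Xc <- stepwedgesim:::sw_design_matrix(trial, time_adjustment)
  p <- ncol(Xc)
  B <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (k in unique(trial$cluster)) {
    idx <- which(trial$cluster == k)
    ni <- trial$n[idx]
    rows <- rep(idx, ni)
    X <- Xc[rows, , drop = FALSE]
    y <- unlist(lapply(idx, function(i)
      c(rep(1, trial$events[i]), rep(0, trial$n[i] - trial$events[i]))))
    mu <- stats::plogis(drop(X %*% beta))
    v <- mu * (1 - mu)
    nk <- length(y)
    Rw <- matrix(wc_alpha, nk, nk); diag(Rw) <- 1
    V <- diag(sqrt(v)) %*% Rw %*% diag(sqrt(v))
    D <- v * X                       # d mu / d beta for logit link
    Vi <- solve(V)
    B <- B + t(D) %*% Vi %*% D
    g <- t(D) %*% Vi %*% (y - mu)
    meat <- meat + g %*% t(g)
  }
  Binv <- solve(B)
  list(bread = B, meat = meat, vcov = Binv %*% meat %*% Binv)
}
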
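test_that("beta shape parameters reproduce the target mean and ICC", {
  bp <- solve_beta_params(0.1, 0.01)
  expect_equal(bp$a, 9.9)
  expect_equal(bp$b, 89.1)
  bp <- solve_beta_params(0.2, 0.1)
  expect_equal(bp$a, 1.8)
  expect_equal(bp$b, 7.2)
  # closed-form recovery of (mu, rho) from any solution, to machine precision
  for (mu in c(0.05, 0.2, 0.5, 0.9)) {
    for (rho in c(0.01, 0.05, 0.3)) {
      bp <- solve_beta_params(mu, rho)
      expect_gt(bp$a, 0)
      expect_gt(bp$b, 0)
      expect_equal(bp$a / (bp$a + bp$b), mu, tolerance = 1e-12)
      expect_equal(1 / (bp$a + bp$b + 1), rho, tolerance = 1e-12)
    }
  }
  # symmetric distribution at mu = 0.5
  bp <- solve_beta_params(0.5, 0.07)
  expect_equal(bp$a, bp$b)
  # numerical check of the beta moments themselves
  bp <- solve_beta_params(0.1, 0.01)
  m1 <- integrate(function(p) p * dbeta(p, bp$a, bp$b), 0, 1)$value
  m2 <- integrate(function(p) p^2 * dbeta(p, bp$a, bp$b), 0, 1)$value
  expect_equal(m1, 0.1, tolerance = 1e-8)
  expect_equal((m2 - m1^2) / (m1 * (1 - m1)), 0.01, tolerance = 1e-8)
  expect_error(solve_beta_params(0, 0.1), "mu")
  expect_error(solve_beta_params(0.5, 1), "rho")
})

test_that("cell probabilities follow the logistic model in treatment and time", {
  # intervention doubles a 0.1 proportion when OR = 2.25
  expect_equal(cell_probability(qlogis(0.1), 1, 0, log(2.25), 0), 0.2)
  # baseline cell recovers the cluster proportion whatever the effects are
  expect_equal(cell_probability(qlogis(0.1), 0, 0, 5, -3), 0.1)
  # two periods of a 1.227 time odds ratio: odds (1/9) * 1.227^2
  odds <- (0.1 / 0.9) * 1.227^2
  expect_equal(cell_probability(qlogis(0.1), 0, 2, 0, log(1.227)),
               odds / (1 + odds), tolerance = 1e-12)
  expect_equal(cell_probability(qlogis(0.1), 0, 2, 0, log(1.227)),
               0.14331, tolerance = 1e-4)
  p <- cell_probability(qlogis(0.3), 1, 3, log(2), log(1.1))
  expect_true(p > 0 && p < 1)
})

test_that("step allocation partitions clusters evenly and uniformly", {
  set.seed(11)
  a <- allocate_steps(3, 3)
  expect_setequal(a, 1:3)
  a <- allocate_steps(6, 3)
  expect_equal(as.integer(table(a)), rep(2L, 3))
  expect_error(allocate_steps(7, 3), "divisible")
  # uniformity: each cluster should land on each switch period equally often
  draws <- replicate(4000, allocate_steps(6, 3))
  counts <- table(cluster = rep(1:6, 4000), step = as.vector(draws))
  chisq <- sum((counts - 4000 / 3)^2 / (4000 / 3))
  # 12 df: 6 clusters x (3 - 1); generous threshold to keep flake risk tiny
  expect_lt(chisq, qchisq(1 - 1e-6, df = 12))
})

test_that("simulated trials satisfy the stepped wedge design invariants", {
  for (seed in 1:20) {
    tr <- small_trial(n_clusters = 6, cell_size = 8, seed = seed)
    # once switched, stays switched; all-control first period, all-treated last
    for (k in unique(tr$cluster)) {
      x <- tr$treatment[tr$cluster == k]
      expect_true(all(diff(x) >= 0))
    }
    expect_true(all(tr$treatment[tr$period == 0] == 0))
    expect_true(all(tr$treatment[tr$period == max(tr$period)] == 1))
    expect_true(all(tr$events >= 0 & tr$events <= tr$n))
    expect_true(all(tr$p_true > 0 & tr$p_true < 1))
    # discard rule: at least one event in each condition
    expect_gt(sum(tr$events[tr$treatment == 0]), 0)
    expect_gt(sum(tr$events[tr$treatment == 1]), 0)
    # canonical lower-triangular wedge after sorting by switch period
    tm <- treatment_matrix(tr)
    expect_true(all(tm[order(rowSums(tm), decreasing = TRUE), ] == tm))
    per_step <- table(attr(tr, "step_allocation"))
    expect_equal(as.integer(per_step), rep(2L, 3))
  }
})

test_that("the generator hits the target mean and ICC in the aggregate", {
  sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 10,
                    baseline_mean = 0.1, icc = 0.05,
                    or_intervention = 1, or_time = 1, replicates = 1)
  streams <- sw_streams(321, 2000)
  props <- numeric(2000)
  p0 <- matrix(NA_real_, 2000, 6)
  for (r in 1:2000) {
    tr <- sw_simulate(sc, stream = streams[[r]])
    props[r] <- sum(tr$events) / sum(tr$n)
    p0[r, ] <- attr(tr, "p0k")
  }
  # with null intervention and time effects, E[grand proportion] = mu
  mc_se <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - 0.1), 3 * mc_se)
  # the drawn cluster proportions carry the designed mean and ICC
  draws <- as.vector(p0)
  expect_lt(abs(mean(draws) - 0.1), 3 * sd(draws) / sqrt(length(draws)))
  icc_hat <- var(draws) / (mean(draws) * (1 - mean(draws)))
  dev2 <- (draws - mean(draws))^2
  icc_se <- sd(dev2) / sqrt(length(dev2)) / (mean(draws) * (1 - mean(draws)))
  expect_lt(abs(icc_hat - 0.05), 3 * icc_se)
})

test_that("observed cluster proportions converge to the drawn truth", {
  sc <- sw_scenario(steps = 3, n_clusters = 3, cell_size = 10000,
                    baseline_mean = 0.1, icc = 0.05,
                    or_intervention = 1, or_time = 1, replicates = 1)
  tr <- sw_simulate(sc, stream = sw_streams(5, 1)[[1]])
  p0k <- attr(tr, "p0k")
  for (k in 1:3) {
    sub <- tr[tr$cluster == k, ]
    obs <- sum(sub$events) / sum(sub$n)
    expect_lt(abs(obs - p0k[k]),
              3 * sqrt(p0k[k] * (1 - p0k[k]) / sum(sub$n)))
  }
})

test_that("a larger intervention effect never lowers an intervention cell probability", {
  st <- sw_streams(77, 1)[[1]]
  make <- function(or) {
    sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 5,
                      baseline_mean = 0.1, icc = 0.05,
                      or_intervention = or, or_time = 1.227, replicates = 1)
    sw_simulate(sc, stream = st)
  }
  ors <- c(1, 1.5, 2.25, 5)
  trials <- lapply(ors, make)
  # common random numbers: identical cluster draws and allocation
  for (i in 2:4) {
    expect_identical(attr(trials[[i]], "p0k"), attr(trials[[1]], "p0k"))
    expect_identical(attr(trials[[i]], "step_allocation"),
                     attr(trials[[1]], "step_allocation"))
    trt <- trials[[1]]$treatment == 1
    expect_true(all(trials[[i]]$p_true[trt] >= trials[[i - 1]]$p_true[trt]))
    expect_identical(trials[[i]]$p_true[!trt], trials[[1]]$p_true[!trt])
  }
})

test_that("generation is reproducible from a stream and flags degenerate scenarios", {
  sc <- sw_scenario(steps = 3, n_clusters = 3, cell_size = 5,
                    baseline_mean = 0.1, icc = 0.05, replicates = 1)
  st <- sw_streams(9, 1)[[1]]
  t1 <- sw_simulate(sc, stream = st)
  t2 <- sw_simulate(sc, stream = st)
  expect_identical(t1, t2)
  # essentially event-free scenario exhausts the retry cap
  sc0 <- sw_scenario(steps = 3, n_clusters = 3, cell_size = 1,
                     baseline_mean = 1e-5, icc = 0.01, replicates = 1)
  expect_error(sw_simulate(sc0, stream = st, max_retries = 25), "degenerate")
})

test_that("trials round-trip through the CSV export", {
  tr <- small_trial(seed = 4)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  back <- read.csv(path)
  expect_equal(back$events, tr$events)
  expect_equal(back$p_true, tr$p_true, tolerance = 1e-12)
  unlink(path)
})
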
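test_that("per cent bias follows its defining formula", {
  expect_equal(percent_bias(rep(0.8920, 5), log(2.25)),
               100 * (0.8920 - log(2.25)) / log(2.25))
  expect_equal(percent_bias(rep(0.8920, 5), log(2.25)), 10, tolerance = 1e-2)
  expect_equal(percent_bias(rep(log(2.25), 3), log(2.25)), 0)
  expect_equal(percent_bias(c(0.07, 0.13, 0.10), 0.1), 0)
  expect_error(percent_bias(numeric(0), 1), "non-empty")
  expect_error(percent_bias(c(1, 2), 0), "non-zero")
})

test_that("rejection rates count p-values strictly below the level", {
  expect_equal(rejection_rate(c(0.03, 0.6, 0.04, 0.2), 0.05), 0.5)
  expect_equal(rejection_rate(rep(1, 10), 0.05), 0)
  expect_equal(rejection_rate(c(0.05, 0.049), 0.05), 0.5)  # strict inequality
  expect_error(rejection_rate(numeric(0)), "non-empty")
  expect_error(rejection_rate(0.3, alpha = 0), "alpha")
  set.seed(14)
  u <- runif(2000)
  expect_lt(abs(rejection_rate(u, 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("scenario summaries aggregate converged fits with the right accounting", {
  sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 20,
                    baseline_mean = 0.1, icc = 0.05,
                    or_intervention = 2.25, or_time = 1,
                    replicates = 30, seed = 71)
  res <- run_scenario(sc, methods = c("gee", "cluster_summaries"),
                      keep_replicates = TRUE)
  expect_equal(nrow(res), 2)
  expect_setequal(res$method, c("gee", "cluster_summaries"))
  reps <- attr(res, "replicates")
  expect_equal(nrow(reps), 60)
  for (m in res$method) {
    row <- res[res$method == m, ]
    sub <- reps[reps$method == m & reps$converged, ]
    expect_equal(row$n_converged, nrow(sub))
    expect_equal(row$rejection_rate, mean(sub$p_value < 0.05))
    expect_equal(row$mc_se_rejection,
                 sqrt(row$rejection_rate * (1 - row$rejection_rate) /
                        row$n_converged))
    truth <- if (m == "cluster_summaries") sc$true_rd else sc$beta1
    est <- if (m == "gee") sub$estimate_conditional else sub$estimate
    expect_equal(row$percent_bias, 100 * (mean(est) - truth) / truth)
  }
  # under the null the log odds ratio truth is zero: bias undefined
  sc0 <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 20,
                     baseline_mean = 0.1, icc = 0.05,
                     or_intervention = 1, or_time = 1,
                     replicates = 5, seed = 72)
  res0 <- run_scenario(sc0, methods = "gee")
  expect_true(is.na(res0$percent_bias))
  expect_false(is.na(res0$rejection_rate))
})

test_that("the factorial grids enumerate the design space", {
  ga <- scenario_a_grid()
  expect_equal(nrow(ga), 240)  # 5 x 4 x 3 x 2 x 2
  expect_equal(nrow(unique(ga)), 240)
  expect_setequal(unique(ga$n_clusters), c(3, 6, 9, 18, 36))
  expect_setequal(unique(ga$cell_size), c(5, 10, 50, 100))
  expect_setequal(unique(ga$icc), c(0.01, 0.05, 0.1))
  expect_setequal(unique(ga$or_time), c(1, 1.227))
  expect_setequal(unique(ga$or_intervention), c(1, 2.25))
  expect_true(all(ga$baseline_mean == 0.1))
  expect_true(all(ga$steps == 3))
  gb <- scenario_b_grid()
  expect_equal(nrow(gb), 192)  # 4 x 4 x 3 x 2 x 2
  expect_true(all(gb$steps == 6))
  expect_true(all(gb$baseline_mean == 0.2))
  expect_setequal(unique(gb$n_clusters), c(6, 12, 18, 36))
  expect_setequal(unique(gb$cell_size), c(5, 10, 25, 50))
  expect_setequal(unique(gb$or_intervention), c(1, 1.33))
  expect_setequal(unique(gb$or_time), c(1, 1.03))
  expect_true(all(gb$n_clusters %% gb$steps == 0))
})

test_that("grid runs are deterministic and ignore ambient RNG state", {
  g <- scenario_a_grid(replicates = 8)[c(1, 61), ]
  r1 <- run_grid(g, methods = c("gee", "fixed_effects"), seed = 5)
  set.seed(999); runif(17)  # perturb the global RNG state
  r2 <- run_grid(g, methods = c("gee", "fixed_effects"), seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4)
  r3 <- run_grid(g, methods = c("gee", "fixed_effects"), seed = 6)
  expect_false(identical(r1$mean_estimate, r3$mean_estimate))
  expect_error(run_grid(g[0, ], seed = 1), "empty")
})

test_that("per-replicate streams make results invariant to execution order", {
  sc1 <- sw_scenario(steps = 3, n_clusters = 3, cell_size = 10,
                     baseline_mean = 0.1, icc = 0.05, replicates = 6,
                     seed = 31)
  a <- run_scenario(sc1, methods = "gee")
  # running another scenario in between must not disturb reproducibility
  run_scenario(sw_scenario(replicates = 3, seed = 99), methods = "gee")
  b <- run_scenario(sc1, methods = "gee")
  expect_identical(a, b)
})

test_that("configuration files expand to scenario grids", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("steps: 3",
               "n_clusters: [3, 6]",
               "cell_size: [10, 50]",
               "baseline_mean: 0.1",
               "icc: 0.05",
               "or_intervention: 2.25",
               "or_time: [1, 1.227]",
               "replicates: 4",
               "seed: 12",
               "methods: [gee, glmm]",
               "time_adjustment: linear"), path)
  cfg <- sw_read_config(path)
  expect_equal(nrow(cfg$grid), 8)
  expect_equal(cfg$methods, c("gee", "glmm"))
  expect_equal(cfg$seed, 12L)
  expect_true(all(cfg$grid$replicates == 4L))
  writeLines("bogus_key: 1", path)
  expect_error(sw_read_config(path), "unknown configuration keys")
  unlink(path)
})

test_that("results export to CSV with a JSON run log", {
  g <- scenario_a_grid(replicates = 4)[c(1, 2), ]
  res <- run_grid(g, methods = "gee", seed = 3)
  csv <- tempfile(fileext = ".csv")
  sw_write_results(res, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$rejection_rate, res$rejection_rate)
  log <- jsonlite::read_json(sub("csv$", "json", csv))
  expect_equal(log$master_seed, 3)
  expect_equal(log$n_scenarios, 2)
  unlink(c(csv, sub("csv$", "json", csv)))
})
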
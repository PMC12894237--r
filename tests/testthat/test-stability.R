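# modest settings keep the re-estimation loops quick
fast_cfg <- estimation_config(n_lambda = 40)

test_that("dropping (almost) no rows reproduces the full-sample centralities", {
  set.seed(61)
  net <- planted_small_net()
  V <- gibbs_sample(net, sim_config(n = 600, burn_in = 50, seed = 61))$values
  res <- case_drop_bootstrap(V, grid = 1e-6, reps = 2, cfg = fast_cfg,
                             seed = 1)
  # the "subsample" is a row permutation of the full data; correlations are
  # 1 up to floating-point summation order in the solver
  expect_equal(res$correlations$cor, rep(1, 4), tolerance = 1e-8)
})

test_that("case-dropping replicates are reproducible under a seed", {
  set.seed(62)
  net <- planted_small_net()
  V <- gibbs_sample(net, sim_config(n = 500, burn_in = 50, seed = 62))$values
  r1 <- case_drop_bootstrap(V, grid = 0.5, reps = 1, cfg = fast_cfg, seed = 7)
  r2 <- case_drop_bootstrap(V, grid = 0.5, reps = 1, cfg = fast_cfg, seed = 7)
  expect_identical(r1$correlations, r2$correlations)
})

test_that("the CS coefficient reads the correlation table correctly", {
  grid <- seq(0.1, 0.75, 0.05)
  # perfectly stable estimator: CS is the largest grid value
  stable <- fake_stability_result(grid, lapply(grid, function(q) rep(1, 40)))
  expect_equal(unname(cs_coefficient(stable)), max(grid))
  # pure noise: CS = 0
  noise <- fake_stability_result(grid, lapply(grid, function(q) rep(0, 40)))
  expect_equal(unname(cs_coefficient(noise)), 0)

  # exactly 95% pass at 0.5, 90% at 0.55 and above -> CS = 0.5
  cors <- lapply(grid, function(q) {
    if (q <= 0.5) c(rep(1, 19), 0) else c(rep(1, 18), 0, 0)
  })
  mixed <- fake_stability_result(grid, cors)
  expect_equal(unname(cs_coefficient(mixed, 0.7, 0.95)), 0.5)

  # monotone in its thresholds: raising either never raises CS
  expect_lte(unname(cs_coefficient(mixed, 0.7, 0.99)),
             unname(cs_coefficient(mixed, 0.7, 0.95)))
  expect_lte(unname(cs_coefficient(mixed, 1.01, 0.95)),
             unname(cs_coefficient(mixed, 0.7, 0.95)))
})

test_that("undefined correlations are flagged, never fatal", {
  # data from an empty network: subsample networks are mostly empty, so the
  # full-sample centrality vector is constant and correlations are NA
  set.seed(63)
  V <- matrix(rbinom(300 * 4, 1, 0.5), 300, 4)
  res <- case_drop_bootstrap(V, grid = 0.3, reps = 3, cfg = fast_cfg, seed = 3)
  expect_true(all(is.na(res$correlations$cor)))
  expect_equal(unname(cs_coefficient(res)), c(0, 0))
})

test_that("edge bootstrap brackets strong edges away from zero", {
  # two disconnected cliques, so cross-component pairs are truly absent
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1.5
  W[3, 4] <- W[4, 3] <- 1.5
  net <- ising_network(W, rep(-0.75, 4))
  V <- gibbs_sample(net, sim_config(n = 1200, burn_in = 50, seed = 64))$values
  eb <- edge_bootstrap(V, reps = 60, cfg = fast_cfg, seed = 9)
  for (pair in list(c("V1", "V2"), c("V3", "V4"))) {
    strong <- eb[eb$source == pair[1] & eb$target == pair[2], ]
    expect_gt(strong$ci_lower, 0)
  }
  expect_true(all(eb$ci_lower <= eb$boot_mean + 1e-12))
  expect_true(all(eb$boot_mean <= eb$ci_upper + 1e-12))
  # a pair selected in no replicate has a degenerate [0, 0] interval
  # (V2--V4 under this seed; verified against the replicate draws)
  absent <- eb[eb$source == "V2" & eb$target == "V4", ]
  expect_equal(c(absent$boot_mean, absent$ci_lower, absent$ci_upper),
               c(0, 0, 0))

  eb2 <- edge_bootstrap(V, reps = 60, cfg = fast_cfg, seed = 9)
  expect_identical(eb, eb2)
})
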
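test_that("threshold perturbation shifts by multiples of sd(tau)", {
  net <- ising_network(matrix(0, 3, 3), c(-1, -2, -3))
  # sd of (-1,-2,-3) is 1; aggravating node 2 by 2 SD gives 0
  up <- perturb_thresholds(net, 2, "aggravate", 2)
  expect_equal(up$tau, c(-1, 0, -3))
  # magnitude 0 is the identity; aggravate then alleviate (relative to the
  # same reference SD) round-trips
  expect_equal(perturb_thresholds(net, 1, "aggravate", 0)$tau, net$tau)
  down <- perturb_thresholds(up, 2, "alleviate", 2, tau_sd = sd(net$tau))
  expect_equal(down$tau, net$tau, tolerance = 1e-12)

  one <- ising_network(matrix(0, 1, 1), -1)
  expect_error(perturb_thresholds(one, 1, "aggravate"), "single-node")
  expect_error(perturb_thresholds(net, "nope"), "unknown node")
})

test_that("simulated sum scores match exact expectations", {
  # 32 fair coins: E[S] = 16
  zero <- ising_network(matrix(0, 32, 32), rep(0, 32))
  sim <- simulate_sum_scores(zero, 4000, sim_config(burn_in = 30), seed = 5)
  se <- sqrt(32 * 0.25 / 4000)
  expect_lt(abs(sim$mean - 16), 3 * se)
  expect_lt(sim$ci_low, sim$mean)
  expect_gt(sim$ci_high, sim$mean)

  # coupled toy network against enumeration
  net <- toy3_net(tau = c(-0.4, 0.2, 0.1))
  es <- exact_mean_sumscore(net)
  sim3 <- simulate_sum_scores(net, 20000, sim_config(burn_in = 50), seed = 6)
  se3 <- sd(sim3$scores) / sqrt(20000)
  expect_lt(abs(sim3$mean - es), 3 * se3)

  s1 <- simulate_sum_scores(net, 100, sim_config(burn_in = 20), seed = 8)
  s2 <- simulate_sum_scores(net, 100, sim_config(burn_in = 20), seed = 8)
  expect_identical(s1$scores, s2$scores)
})

test_that("CI width shrinks like 1/sqrt(n_persons)", {
  net <- chain_net(5, beta = 0.8, tau = -0.5)
  a <- simulate_sum_scores(net, 2000, sim_config(burn_in = 40), seed = 11)
  b <- simulate_sum_scores(net, 8000, sim_config(burn_in = 40), seed = 12)
  ratio <- (a$ci_high - a$ci_low) / (b$ci_high - b$ci_low)
  expect_lt(abs(ratio - 2), 0.3)  # sqrt(8000/2000) = 2, within 15%
})

test_that("run_nira produces one baseline and a rank permutation per direction", {
  net <- chain_net(4, beta = 0.6, tau = -1)
  res <- run_nira(net, magnitude = 1, n_persons = 300,
                  cfg = sim_config(burn_in = 30), seed = 13)
  expect_equal(sum(res$direction == "baseline"), 1)
  expect_setequal(res$rank[res$direction == "aggravate"], 1:4)
  expect_setequal(res$rank[res$direction == "alleviate"], 1:4)
  expect_true(all(res$ci_low <= res$mean & res$mean <= res$ci_high))

  # magnitude 0: every condition shares the baseline distribution, so CIs
  # overlap the baseline CI
  res0 <- run_nira(net, magnitude = 0, n_persons = 400,
                   cfg = sim_config(burn_in = 30), seed = 14)
  base <- res0[res0$direction == "baseline", ]
  others <- res0[res0$direction != "baseline", ]
  expect_true(all(others$ci_low <= base$ci_high & others$ci_high >= base$ci_low))
})

test_that("aggravation raises and alleviation lowers E[S] under positive coupling", {
  # exact enumeration: E[S] is monotone in each threshold when W >= 0
  net <- chain_net(6, beta = 0.9)
  net <- ising_network(net$W, seq(-1.8, -0.6, length.out = 6), net$item_ids)
  base <- exact_mean_sumscore(net)
  for (i in c(1, 4)) {
    up <- exact_mean_sumscore(perturb_thresholds(net, i, "aggravate", 2))
    dn <- exact_mean_sumscore(perturb_thresholds(net, i, "alleviate", 2))
    expect_gte(up, base)
    expect_lte(dn, base)
  }
})
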
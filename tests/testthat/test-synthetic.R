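test_that("planted networks have the requested structure", {
  net <- make_true_network(20, 12, intra_density = 0.15, n_bridges = 3,
                           seed = 1)
  expect_equal(length(net$tau), 32)
  cross <- outer(net$communities, net$communities, `!=`)
  expect_equal(sum(net$W[upper.tri(net$W)] [cross[upper.tri(cross)]] != 0), 3)
  expect_equal(net$W, t(net$W))
  expect_true(all(diag(net$W) == 0))

  # same seed, same network; empty settings give an empty matrix
  net2 <- make_true_network(20, 12, intra_density = 0.15, n_bridges = 3,
                            seed = 1)
  expect_identical(net$W, net2$W)
  empty <- make_true_network(5, 4, intra_density = 0, n_bridges = 0, seed = 2)
  expect_true(all(empty$W == 0))
  expect_error(make_true_network(3, 2, n_bridges = 7), "inter-community")
})

test_that("exact enumeration matches closed forms and normalizes", {
  # independent fair coins
  W0 <- matrix(0, 2, 2)
  d <- exact_distribution(ising_network(W0, c(0, 0)))
  expect_equal(d$prob, rep(0.25, 4))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)

  # p = 2, beta = 1: P(1,1) = e / (3 + e)
  W <- matrix(c(0, 1, 1, 0), 2)
  d2 <- exact_distribution(ising_network(W, c(0, 0)))
  both <- d2$states[, 1] == 1 & d2$states[, 2] == 1
  expect_equal(d2$prob[both], exp(1) / (3 + exp(1)), tolerance = 1e-12)

  d1 <- exact_distribution(ising_network(matrix(0, 1, 1), 0))
  expect_equal(d1$prob, c(0.5, 0.5))

  big <- ising_network(matrix(0, 17, 17), rep(0, 17))
  expect_error(exact_distribution(big), "p <= 16")
})

test_that("enumeration is consistent with the conditional logistic form", {
  set.seed(5)
  net <- make_true_network(3, 2, intra_density = 0.5, n_bridges = 2,
                           weight_range = c(-1, 1), tau_range = c(-1.5, 0.5),
                           seed = 5)
  d <- exact_distribution(net)
  p <- 5
  for (i in 1:p) {
    # group states by x_{-i} and compare conditional P(x_i = 1)
    rest <- d$states[, -i, drop = FALSE]
    key <- apply(rest, 1, paste, collapse = "")
    for (k in unique(key)) {
      idx <- key == k
      pr <- d$prob[idx]
      xi <- d$states[idx, i]
      cond <- sum(pr[xi == 1]) / sum(pr)
      x_rest <- rest[which(idx)[1], ]
      eta <- net$tau[i] + sum(net$W[i, -i] * x_rest)
      expect_equal(cond, plogis(eta), tolerance = 1e-10)
    }
  }
})

test_that("gibbs sampling agrees with enumeration and is reproducible", {
  # fair coins: every marginal near 1/2
  zero <- ising_network(matrix(0, 4, 4), rep(0, 4))
  X <- gibbs_sample(zero, sim_config(n = 10000, burn_in = 30, seed = 9))
  se <- 0.5 / sqrt(10000)
  expect_true(all(abs(colMeans(X$values) - 0.5) < 3 * se))

  # 3-node coupled network against exact marginals
  net <- toy3_net(tau = c(-0.5, 0.3, 0))
  m_exact <- exact_marginals(net)
  Xs <- gibbs_sample(net, sim_config(n = 20000, burn_in = 50, seed = 10))
  m_hat <- colMeans(Xs$values)
  se <- sqrt(m_exact * (1 - m_exact) / 20000)
  expect_true(all(abs(m_hat - m_exact) < 3 * se))

  # determinism and the two chain modes
  X1 <- gibbs_sample(net, sim_config(n = 50, burn_in = 20, seed = 3))
  X2 <- gibbs_sample(net, sim_config(n = 50, burn_in = 20, seed = 3))
  expect_identical(X1$values, X2$values)
  Xc <- gibbs_sample(net, sim_config(n = 50, burn_in = 20, thin = 5,
                                     chains = "single", seed = 3))
  expect_equal(dim(Xc$values), c(50L, 3L))
})

test_that("flipping threshold signs complements marginals when W = 0", {
  tau <- c(-2, -0.7, 0.4, 1.1)
  a <- exact_marginals(ising_network(matrix(0, 4, 4), tau))
  b <- exact_marginals(ising_network(matrix(0, 4, 4), -tau))
  expect_equal(unname(a), unname(1 - b), tolerance = 1e-12)
})

test_that("threshold calibration hits closed-form and simulated targets", {
  # zero-coupling network: logit is exact
  zero <- ising_network(matrix(0, 3, 3), c(1, -1, 2))
  cal <- calibrate_thresholds(zero, rep(0.5, 3), tol = 1e-6)
  expect_equal(cal$tau, rep(0, 3), tolerance = 1e-4)

  one <- ising_network(matrix(0, 1, 1), 0)
  cal1 <- calibrate_thresholds(one, 0.9, tol = 1e-8)
  expect_equal(cal1$tau, log(9), tolerance = 1e-5)

  # coupled network, exact-enumeration path
  net <- toy3_net(tau = c(0, 0, 0))
  targets <- c(0.2, 0.6, 0.85)
  cal3 <- calibrate_thresholds(net, targets, tol = 0.005)
  expect_true(attr(cal3, "converged"))
  expect_lt(max(abs(exact_marginals(cal3) - targets)), 0.005)

  # impossible tolerance in 1 iteration flags non-convergence
  expect_warning(calibrate_thresholds(net, targets, iterations = 1,
                                      tol = 1e-12),
                 "did not reach")
})
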
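test_that("EBIC follows its closed form", {
  # -2*(-100) + 2*ln(100) + 2*0.25*2*ln(9)
  expect_equal(ebic(-100, 2, 100, 10, 0.25),
               200 + 2 * log(100) + 0.5 * 2 * log(9), tolerance = 1e-12)
  expect_equal(ebic(-57.3, 0, 500, 12, 0.25), 114.6)   # k = 0: -2*loglik
  expect_equal(ebic(-80, 3, 200, 8, 0),                # gamma = 0 is BIC
               -2 * -80 + 3 * log(200))
})

test_that("the penalized path solver matches glmnet along a shared path", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  n <- 800
  Z <- matrix(rbinom(n * 5, 1, 0.5), n)
  eta <- -0.5 + Z %*% c(1.2, -0.8, 0.5, 0, 0)
  y <- rbinom(n, 1, plogis(eta))
  lam_max <- max(abs(crossprod(Z, y - mean(y)))) / n
  lams <- exp(seq(log(lam_max), log(lam_max * 0.01), length.out = 60))
  fit <- isingnet:::.lasso_logistic_path(Z, y, lams, 50L, 200L, 1e-7, 30)
  g <- glmnet::glmnet(Z, y, family = "binomial", lambda = lams,
                      standardize = FALSE, thresh = 1e-11)
  expect_lt(max(abs(rbind(fit$intercepts, fit$beta) -
                      as.matrix(coef(g)))), 1e-4)
})

test_that("independent items yield an empty selected model", {
  set.seed(42)
  V <- matrix(rbinom(5000 * 6, 1, 0.5), 5000, 6)
  fn <- fit_node(V, 1)
  expect_equal(fn$k, 0L)
  expect_true(all(fn$coefficients == 0))
  # intercept of the empty model is the closed-form logistic MLE
  expect_equal(fn$intercept, qlogis(mean(V[, 1])), tolerance = 1e-4)
})

test_that("a duplicated column triggers the separation guard, not a crash", {
  set.seed(43)
  x <- rbinom(400, 1, 0.5)
  V <- cbind(x, x, rbinom(400, 1, 0.5))
  expect_warning(fn <- fit_node(V, 1), "truncated")
  expect_true(all(is.finite(fn$coefficients)))
  expect_true(fn$truncated)
})

test_that("path selection agrees with the exhaustive best-subset oracle", {
  set.seed(77)
  net <- chain_net(6, beta = 1.5, tau = -1)
  V <- gibbs_sample(net, sim_config(n = 2000, burn_in = 50, seed = 77))$values
  p <- ncol(V)
  for (i in c(1, 3, 6)) {
    fn <- fit_node(V, i)
    oracle <- exhaustive_ebic_select(V, i)
    expect_equal(selected_neighbors(fn, i, p), oracle$neighbors)
    # penalized-path EBIC can never beat the exhaustive MLE minimum
    expect_gte(fn$ebic[fn$selected], oracle$ebic - 1e-9)
  }
  # node 3's neighbors in the chain are exactly {2, 4}
  fn3 <- fit_node(V, 3)
  expect_equal(selected_neighbors(fn3, 3, p), c(2L, 4L))
})

test_that("estimate_network returns a symmetric network with AND <= OR", {
  set.seed(55)
  net <- chain_net(5, beta = 1.2, tau = -0.5)
  V <- gibbs_sample(net, sim_config(n = 1500, burn_in = 50, seed = 55))$values
  and_net <- estimate_network(V, estimation_config(rule = "AND"))
  or_net <- estimate_network(V, estimation_config(rule = "OR"))
  expect_equal(and_net$W, t(and_net$W))
  expect_true(all(diag(and_net$W) == 0))
  expect_true(all(which(and_net$W != 0) %in% which(or_net$W != 0)))

  # null data: empty network, thresholds near the marginal logits
  set.seed(56)
  V0 <- matrix(rbinom(5000 * 5, 1, 0.35), 5000, 5)
  null_net <- estimate_network(V0)
  expect_true(all(null_net$W == 0))
  # thresholds sit near the intercept-only logistic MLE (a nodewise model
  # may retain a stray predictor even when the AND rule empties W)
  expect_equal(null_net$tau, qlogis(colMeans(V0)), tolerance = 0.05)

  expect_error(estimate_network(cbind(V0, 1L)), "zero-variance")
})
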
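# Small constructed networks and independent oracles shared across tests.

# three-node network with w12 = 0.5, w13 = -0.2, w23 = 0
toy3_net <- function(tau = c(0, 0, 0)) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- -0.2
  ising_network(W, tau, item_ids = c("a", "b", "c"))
}

# chain graph 1-2-3-...-p with constant coupling
chain_net <- function(p, beta = 1.5, tau = -1) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) W[i, i + 1] <- W[i + 1, i] <- beta
  ising_network(W, rep(tau, p), item_ids = paste0("V", seq_len(p)))
}

# small two-community planted network used by stability / comparison tests
planted_small_net <- function(p_a = 4, p_b = 2, beta = 1.2, tau = -1, bridges = 1) {
  make_true_network(p_knowledge = p_a, p_stigma = p_b, intra_density = 0.5,
                    n_bridges = bridges, weight_range = c(beta, beta),
                    tau_range = c(tau, tau), seed = 424242)
}

# Exhaustive best-subset EBIC oracle: unpenalized logistic fits over every
# neighbor subset of node i (p small). Independent of the lasso path code.
exhaustive_ebic_select <- function(V, i, gamma = 0.25) {
  p <- ncol(V)
  cand <- setdiff(seq_len(p), i)
  best <- integer(0)
  best_e <- Inf
  for (k in 0:length(cand)) {
    subsets <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(cand, k), 2)
    for (S in subsets) {
      df <- data.frame(y = V[, i])
      fml <- if (length(S) == 0) y ~ 1 else {
        for (s in seq_along(S)) df[[paste0("x", s)]] <- V[, S[s]]
        stats::as.formula(paste("y ~", paste0("x", seq_along(S), collapse = " + ")))
      }
      fit <- stats::glm(fml, data = df, family = stats::binomial())
      e <- ebic(as.numeric(stats::logLik(fit)), k, nrow(V), p, gamma)
      if (e < best_e - 1e-9) {
        best_e <- e
        best <- sort(as.integer(S))
      }
    }
  }
  list(neighbors = best, ebic = best_e)
}

# selected neighbor set (indices into the full node set) of a fit_node result
selected_neighbors <- function(fn, i, p) {
  others <- setdiff(seq_len(p), i)
  sort(others[fn$coefficients != 0])
}

# construct a stability_result by hand (for CS coefficient fixtures)
fake_stability_result <- function(grid, cors_by_q, metric = "strength") {
  rows <- do.call(rbind, lapply(seq_along(grid), function(gi) {
    v <- cors_by_q[[gi]]
    data.frame(proportion = grid[gi], rep = seq_along(v), metric = metric,
               cor = v, stringsAsFactors = FALSE)
  }))
  structure(list(correlations = rows, n_skipped = 0L, full_network = NULL,
                 grid = grid, reps = max(lengths(cors_by_q)), metrics = metric),
            class = "stability_result")
}
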
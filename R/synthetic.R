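#' Generate a ground-truth two-community Ising network
#'
#' Plants a network with the structure of a knowledge/stigma questionnaire:
#' two communities with dense intra-community connections and a small,
#' exact number of inter-community bridge edges. Each intra-community pair
#' receives an edge independently with probability `intra_density`;
#' exactly `n_bridges` inter-community pairs are connected. Edge weights
#' are drawn uniformly from `weight_range` (a `negative_frac` share has its
#' sign flipped) and thresholds uniformly from `tau_range`.
#'
#' @param p_knowledge,p_stigma community sizes (defaults 20 and 12 items).
#' @param intra_density probability of an edge within a community.
#' @param n_bridges exact number of between-community edges.
#' @param weight_range range of absolute edge weights.
#' @param tau_range range of node thresholds (negative values push
#'   endorsement rates below one half under 0/1 coding).
#' @param negative_frac expected fraction of negative-sign edges.
#' @param seed optional integer seed.
#' @return An [ising_network()] with communities `"knowledge"`/`"stigma"`
#'   and item ids `MHKQ1..` / `Stigma1..`.
#' @export
make_true_network <- function(p_knowledge = 20, p_stigma = 12,
                              intra_density = 0.15, n_bridges = 3,
                              weight_range = c(0.3, 1.2),
                              tau_range = c(-4.5, -1.0),
                              negative_frac = 0, seed = NULL) {
  stopifnot(intra_density >= 0, intra_density <= 1,
            all(is.finite(weight_range)), all(is.finite(tau_range)))
  p <- p_knowledge + p_stigma
  if (n_bridges > p_knowledge * p_stigma)
    stop("n_bridges exceeds the number of inter-community pairs (",
         p_knowledge * p_stigma, ")")
  ids <- c(paste0("MHKQ", seq_len(p_knowledge)),
           paste0("Stigma", seq_len(p_stigma)))
  comm <- c(rep("knowledge", p_knowledge), rep("stigma", p_stigma))

  with_seed(seed, {
    W <- matrix(0, p, p)
    ut <- which(upper.tri(W), arr.ind = TRUE)
    intra <- comm[ut[, 1]] == comm[ut[, 2]]
    on_edge <- logical(nrow(ut))
    on_edge[intra] <- stats::runif(sum(intra)) < intra_density
    inter_idx <- which(!intra)
    if (n_bridges > 0)
      on_edge[sample(inter_idx, n_bridges)] <- TRUE
    ne <- sum(on_edge)
    w <- stats::runif(ne, weight_range[1], weight_range[2])
    if (negative_frac > 0)
      w <- w * ifelse(stats::runif(ne) < negative_frac, -1, 1)
    W[ut[on_edge, , drop = FALSE]] <- w
    W <- W + t(W)
    tau <- stats::runif(p, tau_range[1], tau_range[2])
    ising_network(W, tau, item_ids = ids, communities = comm)
  })
}

#' Simulation configuration for the Gibbs sampler
#'
#' @param n number of retained respondents (rows).
#' @param burn_in Gibbs sweeps before a state is retained.
#' @param thin sweeps between retained states when `chains = "single"`.
#' @param chains `"independent"` (default; one chain per respondent, rows
#'   are i.i.d. persons) or `"single"` (one long chain, thinned).
#' @param seed optional integer seed; the same seed gives identical output.
#' @export
sim_config <- function(n = 1000, burn_in = 1000, thin = 10,
                       chains = c("independent", "single"), seed = NULL) {
  chains <- match.arg(chains)
  stopifnot(n >= 1, burn_in >= 0, thin >= 1)
  structure(list(n = as.integer(n), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), chains = chains, seed = seed),
            class = "sim_config")
}

#' Exact distribution of a small Ising network
#'
#' Enumerates all `2^p` states of
#' `P(x) propto exp(sum_i tau_i x_i + sum_{i<j} w_ij x_i x_j)`; refuses
#' beyond p = 16. Serves as the exact oracle against which the Gibbs
#' sampler and intervention simulations are validated.
#'
#' @param net an [ising_network()].
#' @return List with `states` (2^p x p 0/1 matrix) and `prob` (summing
#'   to 1), class `ising_distribution`.
#' @export
exact_distribution <- function(net) {
  p <- n_nodes(net)
  if (p > 16) stop("exact enumeration is limited to p <= 16 (got p = ", p, ")")
  states <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- net$item_ids
  storage.mode(states) <- "double"
  energy <- as.vector(states %*% net$tau) +
    rowSums((states %*% net$W) * states) / 2
  energy <- energy - max(energy)
  pr <- exp(energy)
  pr <- pr / sum(pr)
  structure(list(states = states, prob = pr), class = "ising_distribution")
}

#' Exact item marginals P(x_i = 1)
#' @param net an [ising_network()] with p <= 16.
#' @return Named numeric vector.
#' @export
exact_marginals <- function(net) {
  d <- exact_distribution(net)
  setNames(as.vector(crossprod(d$states, d$prob)), net$item_ids)
}

#' Exact expected network sum score E[sum_i x_i]
#' @param net an [ising_network()] with p <= 16.
#' @export
exact_mean_sumscore <- function(net) {
  d <- exact_distribution(net)
  sum(rowSums(d$states) * d$prob)
}

#' Gibbs-sample binary responses from an Ising network
#'
#' Fixed-order single-site Gibbs updates with conditional
#' `P(x_i = 1 | x_-i) = plogis(tau_i + sum_j w_ij x_j)`. With
#' `chains = "independent"` every respondent is an independent chain
#' started from `Bernoulli(plogis(tau_i))` and run for `burn_in` sweeps, so
#' rows are i.i.d. draws.
#'
#' @param net an [ising_network()].
#' @param cfg a [sim_config()].
#' @return A [response_matrix()] (zero-variance check disabled: small
#'   samples from extreme thresholds may legitimately be constant).
#' @export
gibbs_sample <- function(net, cfg = sim_config()) {
  stopifnot(inherits(net, "ising_network"), inherits(cfg, "sim_config"))
  X <- with_seed(cfg$seed,
    .gibbs_ising(net$W, net$tau, cfg$n, cfg$burn_in, cfg$thin,
                 cfg$chains == "independent"))
  colnames(X) <- net$item_ids
  response_matrix(X, check_variance = FALSE)
}

#' Calibrate thresholds to target endorsement rates
#'
#' Adjusts `tau` (holding `W` fixed) so that the model's item marginals
#' match `target_marginals`, by iterative logit-scale offset updates:
#' `tau <- tau + damping * (logit(target) - logit(marginal))`. Marginals
#' are computed exactly for p <= 16 and by Gibbs sampling otherwise.
#'
#' @param net an [ising_network()].
#' @param target_marginals vector in (0,1), one per node.
#' @param iterations maximum update steps.
#' @param tol maximum absolute marginal error to accept (default 0.02).
#' @param damping step-size multiplier in (0, 1]; the default 0.6 damps
#'   the oscillation that full steps cause under strong positive coupling.
#' @param n_sim,burn_in Gibbs sample size and burn-in per iteration when
#'   p > 16.
#' @param seed optional integer seed (used only for the Gibbs path).
#' @return The calibrated [ising_network()], with attributes
#'   `achieved_marginals`, `max_error` and `converged`. Warns and returns
#'   the best iterate if `tol` is not reached.
#' @export
calibrate_thresholds <- function(net, target_marginals, iterations = 30,
                                 tol = 0.02, damping = 0.6,
                                 n_sim = 4000, burn_in = 300, seed = NULL) {
  p <- n_nodes(net)
  stopifnot(length(target_marginals) == p,
            all(target_marginals > 0), all(target_marginals < 1))
  exact <- p <= 16
  get_marginals <- function(nn, it) {
    if (exact) return(exact_marginals(nn))
    s <- if (is.null(seed)) NULL else substream_seed(seed, paste0("calib", it))
    colMeans(gibbs_sample(nn, sim_config(n = n_sim, burn_in = burn_in,
                                         seed = s))$values)
  }
  clamp <- function(m) pmin(pmax(m, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))

  tau <- net$tau
  best_tau <- tau
  best_err <- Inf
  best_m <- NULL
  for (it in seq_len(iterations)) {
    cur <- ising_network(net$W, tau, net$item_ids, net$communities)
    m <- get_marginals(cur, it)
    err <- max(abs(m - target_marginals))
    if (err < best_err) {
      best_err <- err
      best_tau <- tau
      best_m <- m
    }
    if (err <= tol) break
    tau <- tau + damping * (stats::qlogis(target_marginals) - stats::qlogis(clamp(m)))
  }
  out <- ising_network(net$W, best_tau, net$item_ids, net$communities)
  attr(out, "achieved_marginals") <- best_m
  attr(out, "max_error") <- best_err
  attr(out, "converged") <- best_err <= tol
  if (best_err > tol)
    warning(sprintf(
      "threshold calibration did not reach tol = %g after %d iterations (max error %.4f); returning best iterate",
      tol, iterations, best_err))
  out
}
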
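#' Estimation settings for the eLasso Ising fit
#'
#' @param gamma EBIC hyperparameter; 0 recovers the ordinary BIC, larger
#'   values select sparser networks. Default 0.25, the conventional choice
#'   for Ising questionnaire networks.
#' @param n_lambda length of the geometric penalty path.
#' @param lambda_min_ratio smallest / largest penalty on the path.
#' @param rule `"AND"` (default; an edge needs both nodewise regressions to
#'   select it) or `"OR"`.
#' @param tol coordinate-descent convergence tolerance.
#' @param beta_cap magnitude guard: the path is truncated with a warning
#'   once any coefficient exceeds this (quasi-separation at small penalty,
#'   e.g. duplicated items). The default 8 is far above plausible pairwise
#'   logit weights but well below where separation drives coefficients.
#' @param maxit_outer,maxit_inner iteration caps for the proximal-Newton /
#'   coordinate-descent solver.
#' @export
estimation_config <- function(gamma = 0.25, n_lambda = 100,
                              lambda_min_ratio = 0.01,
                              rule = c("AND", "OR"), tol = 1e-6,
                              beta_cap = 8, maxit_outer = 50,
                              maxit_inner = 200) {
  rule <- match.arg(rule)
  stopifnot(gamma >= 0, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(gamma = gamma, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, rule = rule,
                 tol = tol, beta_cap = beta_cap,
                 maxit_outer = as.integer(maxit_outer),
                 maxit_inner = as.integer(maxit_inner)),
            class = "estimation_config")
}

#' Extended Bayesian Information Criterion
#'
#' `EBIC = -2 loglik + k log(n) + 2 gamma k log(p - 1)` for a nodewise
#' logistic model with `k` nonzero predictors out of `p - 1` candidates.
#' `gamma = 0` reduces to the BIC.
#'
#' @param loglik model log-likelihood.
#' @param k number of nonzero predictor coefficients.
#' @param n sample size.
#' @param p total number of network nodes (so `p - 1` candidate predictors).
#' @param gamma sparsity hyperparameter, `>= 0`.
#' @export
ebic <- function(loglik, k, n, p, gamma = 0.25) {
  stopifnot(n >= 1, p >= 2, all(k >= 0), gamma >= 0)
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p - 1)
}

# Geometric lambda path anchored at the smallest lambda that zeroes all
# coefficients (standard l1-logistic path construction).
lambda_path <- function(Z, y, n_lambda, lambda_min_ratio) {
  n <- length(y)
  lam_max <- max(abs(crossprod(Z, y - mean(y)))) / n
  if (lam_max <= 0) lam_max <- 1e-3  # y uncorrelated with every column
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = n_lambda))
}

#' Fit one node's penalized logistic regression path
#'
#' Regresses item `i` on all other items along a geometric lambda path,
#' computes the EBIC at every path point (with `k` = number of nonzero
#' coefficients) and selects the EBIC-minimizing penalty; ties go to the
#' larger penalty (sparser model). If quasi-separation drives coefficients
#' beyond `beta_cap`, the path is truncated there with a warning and
#' selection is over the retained prefix.
#'
#' @param X a [response_matrix()] or {0,1} matrix.
#' @param i node (column) index.
#' @param cfg an [estimation_config()].
#' @return List with the path (`lambda`, `intercepts`, `beta`, `loglik`,
#'   `df`, `ebic`), the `selected` index, and the selected model's
#'   `coefficients`, `intercept` and `k`.
#' @export
fit_node <- function(X, i, cfg = estimation_config()) {
  V <- response_values(X)
  y <- as.numeric(V[, i])
  if (length(unique(y)) < 2)
    stop("node ", i, " has a single response category")
  Z <- V[, -i, drop = FALSE]
  storage.mode(Z) <- "double"
  lams <- lambda_path(Z, y, cfg$n_lambda, cfg$lambda_min_ratio)
  fit <- .lasso_logistic_path(Z, y, lams, cfg$maxit_outer, cfg$maxit_inner,
                              cfg$tol, cfg$beta_cap)
  keep <- if (fit$truncated_at > 0) {
    warning(sprintf(
      "node %d: path truncated at lambda index %d (coefficient magnitude guard %g)",
      i, fit$truncated_at, cfg$beta_cap))
    seq_len(fit$truncated_at - 1)
  } else seq_along(lams)
  if (length(keep) == 0)
    stop("node ", i, ": no valid path point before truncation")
  p_total <- ncol(V)
  eb <- ebic(fit$loglik[keep], fit$df[keep], length(y), p_total, cfg$gamma)
  sel <- which.min(eb)  # first index = largest lambda wins ties
  coefs <- setNames(fit$beta[, sel], colnames(V)[-i])
  list(lambda = lams[keep], intercepts = fit$intercepts[keep],
       beta = fit$beta[, keep, drop = FALSE], loglik = fit$loglik[keep],
       df = fit$df[keep], ebic = eb, selected = sel,
       coefficients = coefs, intercept = fit$intercepts[sel],
       k = fit$df[sel], truncated = fit$truncated_at > 0)
}

# Lean estimation core used by bootstrap / permutation loops: returns
# list(W, tau) without constructing classed objects. V must be an integer
# {0,1} matrix with both categories in every column.
estimate_core <- function(V, cfg) {
  p <- ncol(V)
  n <- nrow(V)
  B <- matrix(0, p, p)   # B[i, j]: coefficient of item j in node i's model
  tau <- numeric(p)
  storage.mode(V) <- "double"
  for (i in seq_len(p)) {
    y <- V[, i]
    Z <- V[, -i, drop = FALSE]
    lams <- lambda_path(Z, y, cfg$n_lambda, cfg$lambda_min_ratio)
    fit <- .lasso_logistic_path(Z, y, lams, cfg$maxit_outer, cfg$maxit_inner,
                                cfg$tol, cfg$beta_cap)
    keep <- if (fit$truncated_at > 0) seq_len(fit$truncated_at - 1) else seq_along(lams)
    if (length(keep) == 0) stop("node ", i, ": no valid path point")
    eb <- ebic(fit$loglik[keep], fit$df[keep], n, p, cfg$gamma)
    sel <- which.min(eb)
    B[i, -i] <- fit$beta[, sel]
    tau[i] <- fit$intercepts[sel]
  }
  both <- (B != 0) & (t(B) != 0)
  avg <- (B + t(B)) / 2
  W <- if (cfg$rule == "AND") {
    ifelse(both, avg, 0)
  } else {
    either <- (B != 0) | (t(B) != 0)
    # mean of the nonzero entries: the average where both are present,
    # half the sum equals the single value when only one is
    ifelse(both, avg, ifelse(either, B + t(B), 0))
  }
  diag(W) <- 0
  list(W = W, tau = tau)
}

#' Estimate an Ising network by eLasso
#'
#' Nodewise l1-regularized logistic regression of every item on all others
#' with EBIC penalty selection, symmetrized by the AND rule (edge retained
#' only if both regressions select it; weight = mean of the two
#' coefficients) or the OR rule (mean of the nonzero coefficients). Node
#' thresholds are the intercepts of each node's own selected model.
#' Predictors enter unstandardized on the {0,1} scale, so thresholds are on
#' the natural logit scale of the items.
#'
#' @param X a [response_matrix()] or {0,1} matrix/data frame; every column
#'   must contain both categories.
#' @param cfg an [estimation_config()].
#' @param communities optional node community labels attached to the
#'   result (defaults to labels carried by `X`'s codebook, if any).
#' @return An [ising_network()] with attribute `fit` holding per-node
#'   selected lambda index, EBIC and model size.
#' @export
estimate_network <- function(X, cfg = estimation_config(), communities = NULL) {
  V <- response_values(X)
  cm <- colMeans(V)
  if (any(cm == 0 | cm == 1))
    stop("zero-variance item(s): ",
         paste(colnames(V)[cm == 0 | cm == 1], collapse = ", "))
  p <- ncol(V)
  n <- nrow(V)
  fits <- lapply(seq_len(p), function(i) fit_node(V, i, cfg))
  B <- matrix(0, p, p)
  for (i in seq_len(p)) B[i, -i] <- fits[[i]]$coefficients
  tau <- vapply(fits, `[[`, 0, "intercept")
  both <- (B != 0) & (t(B) != 0)
  avg <- (B + t(B)) / 2
  W <- if (cfg$rule == "AND") {
    ifelse(both, avg, 0)
  } else {
    either <- (B != 0) | (t(B) != 0)
    ifelse(both, avg, ifelse(either, B + t(B), 0))
  }
  diag(W) <- 0
  net <- ising_network(W, tau, item_ids = colnames(V), communities = communities)
  attr(net, "fit") <- data.frame(
    item_id = colnames(V),
    selected_lambda = vapply(fits, function(f) f$lambda[f$selected], 0),
    k = vapply(fits, `[[`, 0L, "k"),
    ebic = vapply(fits, function(f) f$ebic[f$selected], 0),
    truncated = vapply(fits, `[[`, FALSE, "truncated"),
    stringsAsFactors = FALSE
  )
  attr(net, "config") <- cfg
  net
}
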
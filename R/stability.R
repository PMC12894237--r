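#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion `q` in `grid` and each replicate, retains
#' `ceiling((1 - q) * n)` rows sampled without replacement, re-estimates the
#' network, and records the Pearson correlation between the subsample and
#' full-sample centrality vectors (nodes are the units). Replicates whose
#' subsample loses a response category in some column are skipped and
#' counted. Replicates use index-derived sub-seeds, so results are
#' reproducible and independent of execution order.
#'
#' @param X a [response_matrix()] or {0,1} matrix.
#' @param grid drop proportions, default `seq(0.1, 0.75, by = 0.05)`.
#' @param reps replicates per proportion (default 500).
#' @param metrics centrality metrics to track.
#' @param cfg an [estimation_config()].
#' @param communities community labels (required for
#'   `bridge_expected_influence`).
#' @param seed integer seed.
#' @return Object of class `stability_result`: list with `correlations`
#'   (long data frame: proportion, rep, metric, cor), `n_skipped`,
#'   `full_network`, `grid`, `reps`.
#' @export
case_drop_bootstrap <- function(X, grid = seq(0.10, 0.75, by = 0.05),
                                reps = 500,
                                metrics = c("strength", "expected_influence"),
                                cfg = estimation_config(),
                                communities = NULL, seed = NULL) {
  stopifnot(reps >= 1, all(grid > 0), all(grid < 1))
  V <- response_values(X)
  n <- nrow(V)
  metrics <- match.arg(metrics,
    c("strength", "expected_influence", "bridge_expected_influence"),
    several.ok = TRUE)
  if ("bridge_expected_influence" %in% metrics && is.null(communities))
    stop("bridge_expected_influence requires community labels")

  full <- estimate_core(V, cfg)
  full_net <- ising_network(full$W, full$tau, colnames(V), communities)
  full_vals <- metric_values(full_net, metrics, communities)

  rows <- vector("list", length(grid) * reps)
  n_skipped <- 0L
  k <- 0L
  for (gi in seq_along(grid)) {
    q <- grid[gi]
    m_keep <- ceiling((1 - q) * n)
    for (r in seq_len(reps)) {
      sub <- with_seed(
        if (is.null(seed)) NULL else substream_seed(seed, sprintf("cd-%d-%d", gi, r)),
        sample.int(n, m_keep))
      Vs <- V[sub, , drop = FALSE]
      cm <- colMeans(Vs)
      if (any(cm == 0 | cm == 1)) {
        n_skipped <- n_skipped + 1L
        next
      }
      est <- estimate_core(Vs, cfg)
      sub_net <- ising_network(est$W, est$tau, colnames(V), communities)
      sub_vals <- metric_values(sub_net, metrics, communities)
      cors <- vapply(metrics, function(m) safe_cor(full_vals[[m]], sub_vals[[m]]),
                     0.0)
      k <- k + 1L
      rows[[k]] <- data.frame(proportion = q, rep = r, metric = metrics,
                              cor = cors, row.names = NULL,
                              stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, rows[seq_len(k)])
  structure(list(correlations = correlations, n_skipped = n_skipped,
                 full_network = full_net, grid = grid, reps = reps,
                 metrics = metrics),
            class = "stability_result")
}

metric_values <- function(net, metrics, communities) {
  vals <- list()
  for (m in metrics)
    vals[[m]] <- switch(m,
      strength = strength(net),
      expected_influence = expected_influence(net),
      bridge_expected_influence = bridge_expected_influence(net, communities))
  vals
}

# Pearson correlation that degrades gracefully when a vector is constant
# (e.g. an empty re-estimated network): flagged as NA, never an error.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Correlation stability (CS) coefficient
#'
#' The largest drop proportion in the grid at which at least `prob` of the
#' replicates correlate at least `cor_threshold` with the full-sample
#' centralities; 0 if no grid point qualifies. Values above 0.25 indicate
#' acceptable stability, above 0.5 good stability. Replicates with an
#' undefined correlation (degenerate subsample network) count as failures.
#'
#' @param result a `stability_result` from [case_drop_bootstrap()].
#' @param cor_threshold correlation cut-off (default 0.7).
#' @param prob required fraction of replicates meeting it (default 0.95).
#' @return Named numeric vector, one CS value per metric.
#' @export
cs_coefficient <- function(result, cor_threshold = 0.7, prob = 0.95) {
  cr <- result$correlations
  vapply(result$metrics, function(m) {
    ok_q <- vapply(result$grid, function(q) {
      v <- cr$cor[cr$metric == m & cr$proportion == q]
      if (length(v) == 0) return(FALSE)
      mean(!is.na(v) & v >= cor_threshold) >= prob
    }, TRUE)
    if (!any(ok_q)) 0 else max(result$grid[ok_q])
  }, 0.0)
}

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Resamples rows with replacement `reps` times, re-estimates the network,
#' and reports the bootstrap mean and 2.5%/97.5% percentile interval per
#' edge. Degenerate resamples (a column losing a category) are skipped and
#' counted.
#'
#' @param X a [response_matrix()] or {0,1} matrix.
#' @param reps bootstrap replicates (default 500).
#' @param cfg an [estimation_config()].
#' @param seed integer seed.
#' @return Data frame (class `edge_bootstrap`) with one row per node pair:
#'   `source`, `target`, `observed`, `boot_mean`, `ci_lower`, `ci_upper`;
#'   attribute `n_skipped`.
#' @export
edge_bootstrap <- function(X, reps = 500, cfg = estimation_config(),
                           seed = NULL) {
  stopifnot(reps >= 1)
  V <- response_values(X)
  n <- nrow(V)
  p <- ncol(V)
  full <- estimate_core(V, cfg)
  ut <- which(upper.tri(full$W), arr.ind = TRUE)
  boot <- matrix(NA_real_, reps, nrow(ut))
  n_skipped <- 0L
  for (r in seq_len(reps)) {
    idx <- with_seed(
      if (is.null(seed)) NULL else substream_seed(seed, sprintf("eb-%d", r)),
      sample.int(n, n, replace = TRUE))
    Vs <- V[idx, , drop = FALSE]
    cm <- colMeans(Vs)
    if (any(cm == 0 | cm == 1)) {
      n_skipped <- n_skipped + 1L
      next
    }
    Wb <- estimate_core(Vs, cfg)$W
    boot[r, ] <- Wb[ut]
  }
  used <- !is.na(boot[, 1])
  out <- data.frame(
    source = colnames(V)[ut[, 1]],
    target = colnames(V)[ut[, 2]],
    observed = full$W[ut],
    boot_mean = colMeans(boot[used, , drop = FALSE]),
    ci_lower = apply(boot[used, , drop = FALSE], 2, stats::quantile, 0.025),
    ci_upper = apply(boot[used, , drop = FALSE], 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  attr(out, "reps_used") <- sum(used)
  class(out) <- c("edge_bootstrap", "data.frame")
  out
}
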
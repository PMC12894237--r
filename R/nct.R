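#' Global strength of a network
#'
#' Sum of absolute edge weights over the upper triangle,
#' `S = sum_{i<j} |w_ij|`.
#'
#' @param net an [ising_network()].
#' @export
global_strength <- function(net) {
  sum(abs(net$W[upper.tri(net$W)]))
}

#' Permutation-based two-group network comparison
#'
#' Estimates a network per group, then builds null distributions by
#' re-assigning group labels at random (group sizes fixed) and re-running
#' the full eLasso estimation on both pseudo-groups for every permutation.
#' Tests: invariance of global strength (`|S_A - S_B|`), network structure
#' (maximum absolute edge difference), individual edges, and per-node
#' strength and expected influence. P-values use the add-one estimator
#' `p = (#{perm >= obs} + 1) / (n_perm + 1)`; edge and node p-values are
#' additionally Holm-corrected.
#'
#' @param X_A,X_B the two groups' responses ([response_matrix()] or {0,1}
#'   matrices with identical item columns).
#' @param n_perm number of permutations (default 1000).
#' @param cfg an [estimation_config()].
#' @param seed integer seed.
#' @param p_adjust method for the per-edge/per-node families (default
#'   `"holm"`; any [stats::p.adjust()] method).
#' @param max_redraw how often a permutation with a degenerate column may
#'   be redrawn before it is counted as skipped.
#' @return Object of class `nct_result`: observed statistics, permutation
#'   p-values, per-group networks, and bookkeeping (`n_perm`, redraw
#'   count, seed).
#' @export
nct_test <- function(X_A, X_B, n_perm = 1000, cfg = estimation_config(),
                     seed = NULL, p_adjust = "holm", max_redraw = 100) {
  stopifnot(n_perm >= 1)
  VA <- response_values(X_A)
  VB <- response_values(X_B)
  if (!identical(colnames(VA), colnames(VB)))
    stop("both groups must share the same item columns")
  for (nm in c("A", "B")) {
    cm <- colMeans(if (nm == "A") VA else VB)
    if (any(cm == 0 | cm == 1))
      stop("zero-variance item(s) in group ", nm, ": ",
           paste(colnames(VA)[cm == 0 | cm == 1], collapse = ", "))
  }
  nA <- nrow(VA)
  nB <- nrow(VB)
  V <- rbind(VA, VB)
  p <- ncol(V)
  ut <- upper.tri(matrix(0, p, p))

  stat_vec <- function(est) {
    W <- est$W
    c(gs = sum(abs(W[ut])),
      edges = W[ut],
      strength = rowSums(abs(W)),
      ei = rowSums(W))
  }
  ia <- seq_len(nA)
  fit_both <- function(Vperm) {
    ea <- estimate_core(Vperm[ia, , drop = FALSE], cfg)
    eb <- estimate_core(Vperm[-ia, , drop = FALSE], cfg)
    list(a = stat_vec(ea), b = stat_vec(eb))
  }

  obs_a_est <- estimate_core(VA, cfg)
  obs_b_est <- estimate_core(VB, cfg)
  obs_a <- stat_vec(obs_a_est)
  obs_b <- stat_vec(obs_b_est)
  obs_diff <- abs(obs_a - obs_b)
  obs_maxedge <- max(obs_diff[grep("^edges", names(obs_diff))])

  n_idx <- nA + nB
  ge_counts <- numeric(length(obs_diff))
  ge_maxedge <- 0
  n_redrawn <- 0L
  n_done <- 0L
  for (r in seq_len(n_perm)) {
    ok <- FALSE
    for (att in seq_len(max_redraw)) {
      perm <- with_seed(
        if (is.null(seed)) NULL else substream_seed(seed, sprintf("perm-%d-%d", r, att)),
        sample.int(n_idx))
      Vp <- V[perm, , drop = FALSE]
      cma <- colMeans(Vp[ia, , drop = FALSE])
      cmb <- colMeans(Vp[-ia, , drop = FALSE])
      if (any(c(cma, cmb) %in% c(0, 1))) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      ok <- TRUE
      break
    }
    if (!ok) next
    st <- fit_both(Vp)
    d <- abs(st$a - st$b)
    ge_counts <- ge_counts + (d >= obs_diff - 1e-12)
    ge_maxedge <- ge_maxedge + (max(d[grep("^edges", names(d))]) >= obs_maxedge - 1e-12)
    n_done <- n_done + 1L
  }
  pvals <- (ge_counts + 1) / (n_done + 1)
  p_structure <- (ge_maxedge + 1) / (n_done + 1)

  edge_ids <- which(ut, arr.ind = TRUE)
  edge_names <- paste(colnames(V)[edge_ids[, 1]], colnames(V)[edge_ids[, 2]],
                      sep = "--")
  sel <- function(prefix) {
    idx <- grep(paste0("^", prefix), names(obs_diff))
    v <- pvals[idx]
    names(v) <- if (prefix == "edges") edge_names else colnames(V)
    v
  }
  edge_p <- sel("edges")
  strength_p <- sel("strength")
  ei_p <- sel("ei")

  structure(list(
    global_strength = c(A = unname(obs_a["gs"]), B = unname(obs_b["gs"])),
    global_strength_diff = unname(obs_diff["gs"]),
    global_strength_p = unname(pvals[1]),
    max_edge_diff = obs_maxedge,
    structure_p = p_structure,
    edge_diff = setNames(unname(obs_diff[grep("^edges", names(obs_diff))]), edge_names),
    edge_p = edge_p,
    edge_p_adj = stats::p.adjust(edge_p, p_adjust),
    strength_p = strength_p,
    strength_p_adj = stats::p.adjust(strength_p, p_adjust),
    ei_p = ei_p,
    ei_p_adj = stats::p.adjust(ei_p, p_adjust),
    network_A = ising_network(obs_a_est$W, obs_a_est$tau, colnames(V)),
    network_B = ising_network(obs_b_est$W, obs_b_est$tau, colnames(V)),
    n_perm = n_done, n_redrawn = n_redrawn, p_adjust = p_adjust,
    seed = seed
  ), class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("<nct_result> permutation network comparison\n")
  cat(sprintf("  global strength: A = %.3f, B = %.3f, diff = %.3f, p = %.4g\n",
              x$global_strength["A"], x$global_strength["B"],
              x$global_strength_diff, x$global_strength_p))
  cat(sprintf("  structure (max edge diff): %.3f, p = %.4g\n",
              x$max_edge_diff, x$structure_p))
  cat(sprintf("  permutations: %d (redrawn %d)\n", x$n_perm, x$n_redrawn))
  invisible(x)
}
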
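#' Node strength
#'
#' Sum of absolute edge weights attached to each node,
#' `s_i = sum_j |w_ij|`.
#'
#' @param net an [ising_network()].
#' @return Named numeric vector.
#' @export
strength <- function(net) {
  setNames(rowSums(abs(net$W)), net$item_ids)
}

#' One-step expected influence
#'
#' Signed sum of a node's edge weights, `EI_i = sum_j w_ij`. Equal to
#' strength when all weights are non-negative.
#'
#' @param net an [ising_network()].
#' @return Named numeric vector.
#' @export
expected_influence <- function(net) {
  setNames(rowSums(net$W), net$item_ids)
}

#' Bridge expected influence
#'
#' Signed sum of a node's connections to the other community,
#' `BEI_i = sum_{j: community(j) != community(i)} w_ij`. Positive values
#' indicate activating influence across communities (co-endorsement),
#' negative values deactivating influence.
#'
#' @param net an [ising_network()].
#' @param communities community label per node; defaults to the labels
#'   stored in the network. All nodes must be labeled and at least two
#'   distinct communities present.
#' @return Named numeric vector.
#' @export
bridge_expected_influence <- function(net, communities = net$communities) {
  if (is.null(communities)) stop("no community labels available")
  communities <- as.character(communities)
  if (length(communities) != n_nodes(net) || anyNA(communities) ||
      any(communities == ""))
    stop("every node must have a community label")
  if (length(unique(communities)) < 2)
    stop("bridge expected influence needs at least two communities")
  cross <- outer(communities, communities, `!=`)
  setNames(rowSums(net$W * cross), net$item_ids)
}

zscore <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  s <- if (sd_type == "sample") stats::sd(x) else
    sqrt(mean((x - mean(x))^2))
  if (is.na(s) || s == 0) {
    warning("constant metric: z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Centrality table with standardized columns
#'
#' Computes strength, expected influence and (when communities are
#' available) bridge expected influence per node, plus the z-score of each
#' metric across nodes.
#'
#' @param net an [ising_network()].
#' @param communities optional community labels (default: the network's).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`;
#'   the choice is recorded in the `sd_type` attribute.
#' @return Data frame of class `centrality_table`.
#' @export
centrality_table <- function(net, communities = net$communities,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (n_nodes(net) < 2) stop("centrality table needs at least 2 nodes")
  out <- data.frame(
    item_id = net$item_ids,
    community = if (is.null(communities)) NA_character_ else as.character(communities),
    strength = strength(net),
    expected_influence = expected_influence(net),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(communities) && length(unique(communities)) >= 2)
    out$bridge_expected_influence <- bridge_expected_influence(net, communities)
  for (m in intersect(c("strength", "expected_influence",
                        "bridge_expected_influence"), names(out)))
    out[[paste0("z_", m)]] <- zscore(out[[m]], sd_type)
  attr(out, "sd_type") <- sd_type
  class(out) <- c("centrality_table", "data.frame")
  out
}
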
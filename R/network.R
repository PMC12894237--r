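#' Ising network
#'
#' A pairwise binary Markov random field over p items:
#' `P(x) propto exp(sum_i tau_i x_i + sum_{i<j} w_ij x_i x_j)` with
#' `x in {0,1}^p`. `W` holds the pairwise weights (symmetric, zero
#' diagonal), `tau` the node thresholds (intercepts; under 0/1 coding a more
#' negative threshold means a lower endorsement rate), and `communities`
#' optional item-community labels used by bridge centralities.
#'
#' @param W symmetric numeric p x p matrix with zero diagonal.
#' @param tau numeric length-p threshold vector.
#' @param item_ids node labels (default `V1..Vp` or `colnames(W)`).
#' @param communities optional community label per node.
#' @return Object of class `ising_network`.
#' @export
ising_network <- function(W, tau, item_ids = NULL, communities = NULL) {
  W <- as.matrix(W)
  p <- length(tau)
  if (!is.numeric(W) || nrow(W) != p || ncol(W) != p)
    stop("W must be a numeric ", p, " x ", p, " matrix")
  if (!all(is.finite(W)) || !all(is.finite(tau)))
    stop("network parameters must be finite")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  W <- (W + t(W)) / 2
  if (is.null(item_ids)) item_ids <- colnames(W)
  if (is.null(item_ids)) item_ids <- paste0("V", seq_len(p))
  if (length(item_ids) != p) stop("item_ids must have length p")
  if (!is.null(communities)) {
    communities <- as.character(communities)
    if (length(communities) != p) stop("communities must have length p")
  }
  dimnames(W) <- list(item_ids, item_ids)
  structure(list(W = W, tau = as.numeric(tau), item_ids = as.character(item_ids),
                 communities = communities),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  p <- length(x$tau)
  ne <- sum(x$W[upper.tri(x$W)] != 0)
  cat(sprintf("<ising_network> %d nodes, %d edges\n", p, ne))
  if (!is.null(x$communities))
    cat("  communities:", paste(names(table(x$communities)), table(x$communities),
                                sep = "=", collapse = ", "), "\n")
  cat(sprintf("  thresholds in [%.3g, %.3g]\n", min(x$tau), max(x$tau)))
  invisible(x)
}

n_nodes <- function(net) length(net$tau)

# upper-triangle edge list (nonzero only)
edge_list <- function(net) {
  ut <- which(upper.tri(net$W) & net$W != 0, arr.ind = TRUE)
  data.frame(source = net$item_ids[ut[, 1]],
             target = net$item_ids[ut[, 2]],
             weight = net$W[ut],
             stringsAsFactors = FALSE)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Serialize an Ising network
#'
#' Three formats, all lossless round-trips through [read_network()]:
#' * `csv` — an edge list (`source,target,weight`, nonzero upper triangle
#'   only) plus a `<stem>_nodes.csv` sidecar carrying thresholds and
#'   community labels;
#' * `graphml` — one GraphML file with `threshold`/`community` node
#'   attributes and a `weight` edge attribute;
#' * `json` — `{nodes: [{id, threshold, community}], edges: [...]}`.
#' Weights and thresholds are written with 17 significant digits.
#'
#' @param net an [ising_network()].
#' @param path output file.
#' @param format `"csv"`, `"graphml"` or `"json"`; default guessed from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "csv", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "graphml", "json"))
      stop("cannot guess network format from extension: ", path)
  }
  stopifnot(inherits(net, "ising_network"))
  ed <- edge_list(net)
  comm <- if (is.null(net$communities)) rep("", n_nodes(net)) else net$communities

  if (format == "csv") {
    writeLines(c("source,target,weight",
                 sprintf("%s,%s,%s", ed$source, ed$target, fmt_num(ed$weight))),
               path)
    nodes_path <- nodes_sidecar_path(path)
    writeLines(c("id,threshold,community",
                 sprintf("%s,%s,%s", net$item_ids, fmt_num(net$tau), comm)),
               nodes_path)
  } else if (format == "json") {
    obj <- list(
      nodes = data.frame(id = net$item_ids, threshold = net$tau,
                         community = comm, stringsAsFactors = FALSE),
      edges = ed
    )
    jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    write_graphml(net, path, comm)
  }
  invisible(path)
}

nodes_sidecar_path <- function(path) {
  sub("\\.csv$", "_nodes.csv", path, ignore.case = TRUE)
}

write_graphml <- function(net, path, comm) {
  ed <- edge_list(net)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="threshold" for="node" attr.name="threshold" attr.type="double"/>',
    '  <key id="community" for="node" attr.name="community" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph edgedefault="undirected">',
    sprintf(paste0('    <node id="%s"><data key="threshold">%s</data>',
                   '<data key="community">%s</data></node>'),
            esc(net$item_ids), fmt_num(net$tau), esc(comm)),
    if (nrow(ed) > 0)
      sprintf('    <edge source="%s" target="%s"><data key="weight">%s</data></edge>',
              esc(ed$source), esc(ed$target), fmt_num(ed$weight)),
    '  </graph>',
    '</graphml>'
  )
  writeLines(lines, path)
}

#' Read an Ising network written by [write_network()]
#'
#' @param path input file (for `csv`, the edge-list file; the node sidecar
#'   is located next to it).
#' @param format as in [write_network()].
#' @return An [ising_network()].
#' @export
read_network <- function(path, format = c("auto", "csv", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "graphml", "json"))
      stop("cannot guess network format from extension: ", path)
  }
  if (format == "csv") {
    ed <- utils::read.csv(path, stringsAsFactors = FALSE)
    nd <- utils::read.csv(nodes_sidecar_path(path), stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
    build_network_from_parts(nd, ed)
  } else if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    nd <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    ed <- if (length(obj$edges) == 0) {
      data.frame(source = character(), target = character(), weight = numeric())
    } else as.data.frame(obj$edges, stringsAsFactors = FALSE)
    build_network_from_parts(nd, ed)
  } else {
    read_graphml(path)
  }
}

build_network_from_parts <- function(nd, ed) {
  p <- nrow(nd)
  ids <- as.character(nd$id)
  W <- matrix(0, p, p, dimnames = list(ids, ids))
  if (nrow(ed) > 0) {
    i <- match(as.character(ed$source), ids)
    j <- match(as.character(ed$target), ids)
    if (anyNA(i) || anyNA(j)) stop("edge references unknown node id")
    W[cbind(i, j)] <- as.numeric(ed$weight)
    W[cbind(j, i)] <- as.numeric(ed$weight)
  }
  comm <- as.character(nd$community)
  if (all(is.na(comm)) || all(comm == "")) comm <- NULL
  ising_network(W, as.numeric(nd$threshold), item_ids = ids, communities = comm)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_data <- function(x, key) {
    v <- xml2::xml_text(xml2::xml_find_first(
      x, sprintf(".//g:data[@key='%s']", key), ns))
    v
  }
  nd <- data.frame(
    id = xml2::xml_attr(nodes, "id"),
    threshold = as.numeric(vapply(nodes, get_data, "", key = "threshold")),
    community = vapply(nodes, get_data, "", key = "community"),
    stringsAsFactors = FALSE
  )
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  ed <- data.frame(
    source = xml2::xml_attr(edges, "source"),
    target = xml2::xml_attr(edges, "target"),
    weight = as.numeric(vapply(edges, get_data, "", key = "weight")),
    stringsAsFactors = FALSE
  )
  build_network_from_parts(nd, ed)
}
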
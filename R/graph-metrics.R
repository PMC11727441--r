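#' Global and nodal topology of a binary network
#'
#' One-pass computation of the standard binary-graph metrics used in
#' functional connectome analysis: clustering coefficient (Cp / NCp),
#' characteristic path length (Lp / NLp), global and local efficiency
#' (Eglob, Eloc / Ne, Nle), betweenness centrality (BC) and degree
#' centrality (DC).
#'
#' Path lengths average over reachable pairs only; the number of excluded
#' unreachable ordered pairs is reported so near-disconnection can be
#' audited. Nodes of degree < 2 take clustering and local efficiency 0.
#' Betweenness counts shortest-path fractions over unordered pairs,
#' unnormalized; set `normalize = TRUE` to divide by (N-1)(N-2)/2.
#'
#' @param net a [binary_network()].
#' @param betweenness,local compute betweenness / local-efficiency blocks
#'   (both relatively expensive; switched off for null ensembles).
#' @param normalize normalize betweenness to \[0, 1\].
#' @return Object of class `graph_metrics`: scalars `cp`, `lp`, `eglob`,
#'   `eloc`, count `unreachable_pairs`, and data frame `nodal` with columns
#'   `node`, `dc`, `ncp`, `nlp`, `ne`, `nle`, `bc`.
#' @examples
#' gm <- network_metrics(ring_lattice(20, 4))
#' gm$cp  # 0.5
#' @export
network_metrics <- function(net, betweenness = TRUE, local = TRUE,
                            normalize = FALSE) {
  stopifnot(inherits(net, "binary_network"))
  res <- graph_metrics_cpp(net$adj, betweenness, local)
  n <- net$n_nodes
  bc <- if (betweenness) res$bc else rep(NA_real_, n)
  if (betweenness && normalize && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  nodal <- data.frame(
    node = net$node_names,
    dc = res$deg,
    ncp = res$ncp,
    nlp = res$nlp,
    ne = res$ne,
    nle = if (local) res$nle else rep(NA_real_, n),
    bc = bc)
  structure(
    list(cp = res$cp, lp = res$lp, eglob = res$eglob,
         eloc = if (local) res$eloc else NA_real_,
         unreachable_pairs = res$unreachable_pairs, nodal = nodal,
         sparsity = net$sparsity),
    class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("graph_metrics: Cp %.4f  Lp %.4f  Eglob %.4f  Eloc %.4f\n",
              x$cp, x$lp, x$eglob, x$eloc))
  if (x$unreachable_pairs > 0)
    cat(sprintf("  (%d unreachable ordered pairs excluded from Lp)\n",
                as.integer(x$unreachable_pairs)))
  invisible(x)
}

#' Pairwise shortest-path distances
#'
#' Unweighted breadth-first distances between all node pairs; unreachable
#' pairs are `Inf`.
#'
#' @param net a `binary_network`.
#' @return N x N numeric matrix, zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- bfs_distances_cpp(net$adj)
  dimnames(d) <- list(net$node_names, net$node_names)
  d
}

#' Nodal clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected;
#' 0 for nodes of degree < 2. The network clustering coefficient Cp is the
#' mean over nodes.
#'
#' @param net a `binary_network`.
#' @param v optional node index or name; default all nodes.
#' @return Numeric vector of NCp values.
#' @export
nodal_clustering <- function(net, v = NULL) {
  x <- network_metrics(net, betweenness = FALSE, local = FALSE)$nodal
  out <- setNames(x$ncp, x$node)
  if (is.null(v)) out else out[v]
}

#' Characteristic path length
#'
#' Mean shortest-path distance over reachable ordered pairs. Errors when no
#' pair is reachable (empty graph).
#'
#' @param net a `binary_network`.
#' @return Scalar Lp.
#' @export
characteristic_path_length <- function(net) {
  m <- network_metrics(net, betweenness = FALSE, local = FALSE)
  if (is.na(m$lp)) stop("no reachable node pair: characteristic path length undefined")
  m$lp
}

#' Nodal characteristic path length
#'
#' Mean distance from a node to the nodes reachable from it; `NA` for
#' isolated nodes (excluded from downstream group statistics).
#'
#' @inheritParams nodal_clustering
#' @return Numeric vector of NLp values.
#' @export
nodal_path_length <- function(net, v = NULL) {
  x <- network_metrics(net, betweenness = FALSE, local = FALSE)$nodal
  out <- setNames(x$nlp, x$node)
  if (is.null(v)) out else out[v]
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over node pairs, with 1/Inf = 0;
#' robust to disconnection.
#'
#' @param net a `binary_network`.
#' @return Scalar Eglob in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  network_metrics(net, betweenness = FALSE, local = FALSE)$eglob
}

#' Nodal efficiency
#'
#' Mean inverse distance from a node to every other node.
#'
#' @inheritParams nodal_clustering
#' @return Numeric vector of Ne values in \[0, 1\].
#' @export
nodal_efficiency <- function(net, v = NULL) {
  x <- network_metrics(net, betweenness = FALSE, local = FALSE)$nodal
  out <- setNames(x$ne, x$node)
  if (is.null(v)) out else out[v]
}

#' Local efficiency
#'
#' Network local efficiency Eloc: mean over nodes of the global efficiency
#' of each node's neighbour-induced subgraph (the node itself removed), a
#' fault-tolerance measure of segregation.
#'
#' @param net a `binary_network`.
#' @return Scalar Eloc in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  network_metrics(net, betweenness = FALSE, local = TRUE)$eloc
}

#' Nodal local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours; 0 for
#' degree < 2.
#'
#' @inheritParams nodal_clustering
#' @return Numeric vector of Nle values in \[0, 1\].
#' @export
nodal_local_efficiency <- function(net, v = NULL) {
  x <- network_metrics(net, betweenness = FALSE, local = TRUE)$nodal
  out <- setNames(x$nle, x$node)
  if (is.null(v)) out else out[v]
}

#' Betweenness centrality
#'
#' Sum over unordered node pairs of the fraction of shortest paths passing
#' through each node (Brandes' algorithm); unnormalized by default.
#'
#' @inheritParams network_metrics
#' @param v optional node index or name; default all nodes.
#' @return Numeric vector of BC values.
#' @export
betweenness_centrality <- function(net, v = NULL, normalize = FALSE) {
  x <- network_metrics(net, betweenness = TRUE, local = FALSE,
                       normalize = normalize)$nodal
  out <- setNames(x$bc, x$node)
  if (is.null(v)) out else out[v]
}

#' Degree centrality
#'
#' Number of direct connections of each node.
#'
#' @inheritParams nodal_clustering
#' @return Integer-valued numeric vector of degrees.
#' @export
degree_centrality <- function(net, v = NULL) {
  stopifnot(inherits(net, "binary_network"))
  out <- setNames(as.numeric(rowSums(net$adj)), net$node_names)
  if (is.null(v)) out else out[v]
}
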
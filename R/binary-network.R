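#' Binary undirected network
#'
#' Container for an unweighted, undirected graph on a fixed node set, the
#' object on which all topological metrics are computed. Stored as a 0/1
#' adjacency matrix with an optional sparsity tag recording the threshold
#' that produced it.
#'
#' @param adj square symmetric 0/1 matrix (diagonal ignored).
#' @param sparsity sparsity level S that produced the network, or `NA`.
#' @param node_names optional character vector of node labels.
#' @return An object of class `binary_network` with elements `n_nodes`,
#'   `adj`, `sparsity`, `node_names`.
#' @examples
#' net <- binary_network(matrix(c(0, 1, 1, 0), 2))
#' degree_centrality(net)
#' @export
binary_network <- function(adj, sparsity = NA_real_, node_names = NULL) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  storage.mode(adj) <- "integer"
  adj[is.na(adj)] <- 0L
  adj[adj != 0L] <- 1L
  diag(adj) <- 0L
  if (!isTRUE(all(adj == t(adj)))) stop("adjacency matrix must be symmetric")
  if (is.null(node_names)) {
    node_names <- rownames(adj)
    if (is.null(node_names)) node_names <- paste0("n", seq_len(nrow(adj)))
  }
  dimnames(adj) <- list(node_names, node_names)
  structure(
    list(n_nodes = nrow(adj), adj = adj, sparsity = sparsity,
         node_names = node_names),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges%s\n",
              x$n_nodes, n_edges(x),
              if (is.na(x$sparsity)) "" else sprintf(" (sparsity %.3f)", x$sparsity)))
  invisible(x)
}

#' Number of edges of a binary network
#' @param net a `binary_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  as.integer(sum(net$adj[upper.tri(net$adj)]))
}

#' Edge list of a binary network
#' @param net a `binary_network`.
#' @return Two-column integer matrix of node-index pairs, i < j.
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(upper.tri(net$adj) & net$adj == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}

#' Coerce to a binary network
#'
#' Accepts an adjacency matrix or an `igraph` graph.
#'
#' @param x object to coerce.
#' @param ... passed to [binary_network()].
#' @return A `binary_network`.
#' @export
as_binary_network <- function(x, ...) {
  if (inherits(x, "binary_network")) return(x)
  if (inherits(x, "igraph")) {
    adj <- as.matrix(igraph::as_adjacency_matrix(x, sparse = FALSE))
    return(binary_network(adj, ...))
  }
  binary_network(as.matrix(x), ...)
}

#' Ring lattice graph
#'
#' Regular ring lattice in which every node is joined to its `k/2` nearest
#' neighbours on each side; the classic regular end of the small-world
#' spectrum, with closed-form clustering 3(k-2) / (4(k-1)).
#'
#' @param n number of nodes.
#' @param k even neighbourhood degree.
#' @return A `binary_network`.
#' @examples
#' mean(nodal_clustering(ring_lattice(20, 4)))  # 0.5
#' @export
ring_lattice <- function(n, k) {
  stopifnot(n >= 3, k >= 2, k %% 2 == 0, k < n)
  adj <- matrix(0L, n, n)
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  binary_network(adj)
}
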
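#' Null-ensemble configuration
#'
#' Parameters of the degree-preserving random reference ensemble used to
#' normalize clustering and path length. Defaults (100 networks, 10
#' attempted double-edge swaps per edge) are the field-standard choices.
#'
#' @param n_rand number of random networks (>= 1).
#' @param swaps_per_edge attempted swaps per edge during rewiring (>= 1).
#' @param seed optional integer seed making the ensemble reproducible.
#' @return Object of class `null_config`.
#' @export
null_config <- function(n_rand = 100, swaps_per_edge = 10, seed = NULL) {
  stopifnot(n_rand >= 1, swaps_per_edge >= 1)
  structure(list(n_rand = as.integer(n_rand),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = seed),
            class = "null_config")
}

#' Degree-preserving random reference networks
#'
#' Generates `n_rand` randomized versions of a network by repeated
#' double-edge swaps (Maslov-Sneppen rewiring) that preserve the degree
#' sequence exactly, rejecting swaps that would create self-loops or
#' multi-edges. Graphs admitting no valid swap (complete graphs, stars)
#' come back unchanged; for non-complete graphs this raises a warning.
#'
#' @param net a [binary_network()].
#' @param cfg a [null_config()].
#' @return List of `n_rand` binary networks with the same degree sequence.
#' @export
rewire_preserving_degrees <- function(net, cfg = null_config()) {
  stopifnot(inherits(net, "binary_network"), inherits(cfg, "null_config"))
  ne <- n_edges(net)
  if (ne < 2) stop("rewiring requires at least 2 edges")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected")
  niter <- cfg$swaps_per_edge * ne
  nulls <- vector("list", cfg$n_rand)
  changed <- FALSE
  for (i in seq_len(cfg$n_rand)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    adj <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    if (!changed && any(adj != net$adj)) changed <- TRUE
    nulls[[i]] <- binary_network(adj, sparsity = net$sparsity,
                                 node_names = net$node_names)
  }
  n <- net$n_nodes
  complete <- ne == n * (n - 1) / 2
  if (!changed && !complete)
    warning("no valid degree-preserving swap found; null networks equal the input")
  nulls
}

#' Small-world metrics gamma, lambda, sigma
#'
#' Normalizes the clustering coefficient and characteristic path length of
#' a network by their means over a degree-preserving random ensemble:
#' gamma = Cp / <Cp_rand>, lambda = Lp / <Lp_rand>, sigma = gamma / lambda.
#' A small-world network shows gamma > 1 with lambda close to 1, hence
#' sigma conventionally > 1.1. Null path lengths use the same
#' reachable-pairs convention as [network_metrics()].
#'
#' @param net a [binary_network()].
#' @param cfg a [null_config()].
#' @param nulls optional pre-computed null list (from
#'   [rewire_preserving_degrees()]); otherwise generated from `cfg`.
#' @return Object of class `small_world`: `gamma`, `lambda`, `sigma`,
#'   `cp`, `lp`, and null ensemble summaries `null_cp_mean`, `null_cp_sd`,
#'   `null_lp_mean`, `null_lp_sd`, `n_rand`.
#' @export
small_world <- function(net, cfg = null_config(), nulls = NULL) {
  stopifnot(inherits(net, "binary_network"))
  m <- graph_metrics_cpp(net$adj, FALSE, FALSE)
  if (is.na(m$lp)) stop("no reachable node pair: path length undefined")
  if (is.null(nulls)) nulls <- rewire_preserving_degrees(net, cfg)
  null_cp <- null_lp <- numeric(length(nulls))
  for (i in seq_along(nulls)) {
    nm <- graph_metrics_cpp(nulls[[i]]$adj, FALSE, FALSE)
    null_cp[i] <- nm$cp
    null_lp[i] <- nm$lp
  }
  mcp <- mean(null_cp)
  mlp <- mean(null_lp)
  if (mcp == 0)
    stop("mean null clustering is zero: network too sparse to normalize")
  gamma <- m$cp / mcp
  lambda <- m$lp / mlp
  structure(
    list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         cp = m$cp, lp = m$lp,
         null_cp_mean = mcp, null_cp_sd = sd(null_cp),
         null_lp_mean = mlp, null_lp_sd = sd(null_lp),
         n_rand = length(nulls)),
    class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf(
    "small_world: gamma %.3f  lambda %.3f  sigma %.3f  (%d nulls)\n",
    x$gamma, x$lambda, x$sigma, x$n_rand))
  invisible(x)
}
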
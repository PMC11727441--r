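#' Pearson connectivity matrix from ROI time series
#'
#' Computes the sample Pearson correlation between every pair of ROI time
#' courses, the edge-weight matrix of the functional connectome. The
#' diagonal is reported as 1 but is never a candidate edge.
#'
#' @param timeseries numeric T x N matrix, one column per ROI.
#' @return An N x N symmetric correlation matrix of class `fc_matrix`,
#'   with ROI names in the dimnames.
#' @examples
#' ts <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5))
#' pearson_matrix(ts)["a", "b"]  # 0.9827
#' @export
pearson_matrix <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3)
    stop("at least 3 time points are required to estimate correlations")
  if (anyNA(timeseries)) stop("time series contains missing values")
  sds <- apply(timeseries, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(timeseries)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant ROI time series (zero variance): ",
         paste(bad, collapse = ", "))
  }
  r <- cor(timeseries)
  if (is.null(colnames(r))) {
    nm <- paste0("roi", seq_len(ncol(r)))
    dimnames(r) <- list(nm, nm)
  }
  class(r) <- c("fc_matrix", class(r))
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# upper-triangle pair order used for ranking and tie-breaking:
# lexicographic (i, j), i < j
.pair_index <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))
  cbind(i = i, j = j)
}

# round half away from zero (base round() is banker's)
.round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix at a sparsity threshold
#'
#' Sparsity S is the fraction of realized edges out of all N(N-1)/2 node
#' pairs. The K = round(S * N(N-1)/2) pairs with the strongest correlation
#' are kept as edges, using a subject-specific cutoff so every subject's
#' network has the same number of nodes and edges. Ranking is by absolute
#' correlation by default (`mode = "positive"` ranks signed values);
#' ties are broken by lexicographic node-pair order so results are
#' bit-reproducible.
#'
#' @param m correlation matrix (from [pearson_matrix()]).
#' @param s sparsity in (0, 1).
#' @param mode `"absolute"` (default) or `"positive"` edge ranking.
#' @return A [binary_network()] with `sparsity = s`.
#' @export
binarize_at_sparsity <- function(m, s, mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  m <- unclass(as.matrix(m))
  n <- nrow(m)
  stopifnot(n == ncol(m), s > 0, s < 1)
  npairs <- n * (n - 1) / 2
  k <- .round_half_up(s * npairs)
  if (k < 1) stop("sparsity ", s, " keeps zero edges (degenerate network)")
  pairs <- .pair_index(n)
  w <- m[cbind(pairs[, 1], pairs[, 2])]
  if (mode == "absolute") w <- abs(w)
  keep <- order(-w, pairs[, 1], pairs[, 2])[seq_len(k)]
  adj <- matrix(0L, n, n)
  adj[pairs[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  binary_network(adj, sparsity = s, node_names = rownames(m))
}

#' Size of the largest connected component
#'
#' @param net a `binary_network`.
#' @return Integer node count of the largest component.
#' @export
largest_component_size <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  component_sizes_cpp(net$adj)[1]
}

#' Sparsity threshold grid
#'
#' Default grid 0.05-0.18 in steps of 0.01, the conventional small-world
#' regime for 90-node functional networks.
#'
#' @param s_min,s_max grid bounds.
#' @param step constant grid step.
#' @return Numeric vector of thresholds.
#' @export
sparsity_grid <- function(s_min = 0.05, s_max = 0.18, step = 0.01) {
  stopifnot(s_min > 0, s_max < 1, s_min < s_max, step > 0)
  round(seq(s_min, s_max, by = step), 10)
}

#' Determine the small-world sparsity regime of a cohort
#'
#' Scans a candidate threshold grid and keeps the maximal contiguous run of
#' thresholds on which, for every subject, (1) the mean degree of the
#' binarized network exceeds `2 * log(N)` and (2) the small-world
#' coefficient sigma exceeds `sigma_min`. If several runs tie in length the
#' lowest-sparsity run is returned.
#'
#' @param matrices list of per-subject correlation matrices.
#' @param grid ascending candidate thresholds with constant step.
#' @param null_cfg a [null_config()] for the sigma computation.
#' @param sigma_min small-world criterion (default 1.1).
#' @param log_base base of the logarithm in the degree floor `2 * log(N)`;
#'   default natural log.
#' @param mode edge-ranking mode passed to [binarize_at_sparsity()].
#' @return Object of class `sparsity_regime`: `grid`, logical `pass` matrix
#'   (threshold x condition), `s_min`, `s_max`, `degree_floor`, and a
#'   per-threshold diagnostic table `detail`.
#' @export
determine_regime <- function(matrices, grid = sparsity_grid(),
                             null_cfg = null_config(),
                             sigma_min = 1.1, log_base = exp(1),
                             mode = "absolute") {
  stopifnot(length(matrices) >= 1, length(grid) >= 1)
  steps <- diff(grid)
  if (length(steps) && max(abs(steps - steps[1])) > 1e-9)
    stop("candidate grid must have a constant step")
  if (is.unsorted(grid, strictly = TRUE)) stop("candidate grid must be ascending")
  n <- nrow(matrices[[1]])
  floor_deg <- 2 * log(n, base = log_base)

  min_deg <- matrix(NA_real_, length(grid), length(matrices))
  min_sig <- matrix(NA_real_, length(grid), length(matrices))
  for (si in seq_along(grid)) {
    for (mi in seq_along(matrices)) {
      net <- binarize_at_sparsity(matrices[[mi]], grid[si], mode = mode)
      min_deg[si, mi] <- 2 * n_edges(net) / net$n_nodes
      min_sig[si, mi] <- small_world(net, null_cfg)$sigma
    }
  }
  deg_ok <- apply(min_deg > floor_deg, 1, all)
  sig_ok <- apply(min_sig > sigma_min, 1, all)
  ok <- deg_ok & sig_ok

  detail <- data.frame(
    s = grid,
    mean_degree_min = apply(min_deg, 1, min),
    sigma_min_subject = apply(min_sig, 1, min),
    degree_ok = deg_ok, sigma_ok = sig_ok, pass = ok)

  if (!any(ok)) {
    stop("no threshold satisfies both regime conditions ",
         sprintf("(degree floor %.3f, sigma > %.2f); ", floor_deg, sigma_min),
         "worst-case diagnostics: min mean degree ",
         sprintf("%.2f", max(detail$mean_degree_min)),
         ", max per-threshold min sigma ",
         sprintf("%.3f", max(detail$sigma_min_subject)))
  }
  # maximal contiguous run of TRUE; ties -> lowest S
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  dimnames(min_deg) <- dimnames(min_sig) <-
    list(format(grid), names(matrices) %||% seq_along(matrices))
  structure(
    list(grid = grid[idx], s_min = grid[idx[1]], s_max = grid[idx[length(idx)]],
         degree_floor = floor_deg, sigma_min = sigma_min,
         candidate_grid = grid, detail = detail,
         degree_by_subject = min_deg, sigma_by_subject = min_sig),
    class = "sparsity_regime")
}

#' @export
print.sparsity_regime <- function(x, ...) {
  cat(sprintf(
    "small-world sparsity regime: %.2f-%.2f (%d thresholds; degree floor %.2f, sigma > %.2f)\n",
    x$s_min, x$s_max, length(x$grid), x$degree_floor, x$sigma_min))
  invisible(x)
}
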
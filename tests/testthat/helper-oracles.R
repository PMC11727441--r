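# Independent brute-force oracles, deliberately naive: Floyd-Warshall
# distances, direct triangle counts, shortest-path counting by dynamic
# programming over distances. Used to validate the package's metric engine.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_clustering <- function(adj, v) {
  nb <- which(adj[v, ] == 1)
  k <- length(nb)
  if (k < 2) return(0)
  links <- sum(adj[nb, nb]) / 2
  2 * links / (k * (k - 1))
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  diag(d) <- NA
  vals <- d[!is.na(d) & is.finite(d) & d > 0]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

oracle_nlp <- function(adj, v) {
  d <- oracle_distances(adj)[v, -v]
  vals <- d[is.finite(d)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

oracle_eglob <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_ne <- function(adj, v) {
  n <- nrow(adj)
  d <- oracle_distances(adj)[v, -v]
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n - 1)
}

oracle_nle <- function(adj, v) {
  nb <- which(adj[v, ] == 1)
  if (length(nb) < 2) return(0)
  oracle_eglob(adj[nb, nb, drop = FALSE])
}

# shortest-path counts sigma[s, t] by DP over Floyd-Warshall distances
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (v == s || v == t || !is.finite(d[s, t])) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc
}

# largest component by repeated label contraction (n small in tests)
oracle_largest_component <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] == 1 && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  max(table(comp))
}

random_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a + t(a)
}

# piecewise-linear quadrature oracle: refine each panel into k equal
# sub-intervals (exact for a piecewise-linear interpolant)
oracle_auc <- function(values, thresholds, k = 50) {
  f <- approxfun(thresholds, values)
  xs <- unique(unlist(lapply(seq_len(length(thresholds) - 1), function(i)
    seq(thresholds[i], thresholds[i + 1], length.out = k + 1))))
  ys <- f(xs)
  sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
}

expect_metrics_match_oracle <- function(adj, tol = 1e-10) {
  net <- binary_network(adj)
  gm <- network_metrics(net, betweenness = TRUE, local = TRUE)
  n <- nrow(adj)
  expect_equal(gm$nodal$dc, rowSums(adj), ignore_attr = TRUE)
  expect_equal(gm$nodal$ncp,
               vapply(seq_len(n), function(v) oracle_clustering(adj, v),
                      numeric(1)), tolerance = tol)
  expect_equal(gm$cp, mean(vapply(seq_len(n), function(v)
    oracle_clustering(adj, v), numeric(1))), tolerance = tol)
  expect_equal(gm$lp, oracle_lp(adj), tolerance = tol)
  expect_equal(gm$nodal$nlp,
               vapply(seq_len(n), function(v) oracle_nlp(adj, v),
                      numeric(1)), tolerance = tol)
  expect_equal(gm$eglob, oracle_eglob(adj), tolerance = tol)
  expect_equal(gm$nodal$ne,
               vapply(seq_len(n), function(v) oracle_ne(adj, v),
                      numeric(1)), tolerance = tol)
  expect_equal(gm$nodal$nle,
               vapply(seq_len(n), function(v) oracle_nle(adj, v),
                      numeric(1)), tolerance = tol)
  expect_equal(gm$eloc, mean(vapply(seq_len(n), function(v)
    oracle_nle(adj, v), numeric(1))), tolerance = tol)
  expect_equal(gm$nodal$bc, oracle_betweenness(adj), tolerance = 1e-8)
}
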
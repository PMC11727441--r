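test_that("pearson_matrix reproduces hand-computed correlations", {
  ts <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5), c = -c(1, 2, 3, 4))
  r <- pearson_matrix(ts)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "b"], 0.9827076, tolerance = 1e-6)
  expect_equal(unclass(r), t(unclass(r)), ignore_attr = TRUE)
})

test_that("pearson_matrix agrees with a two-pass covariance oracle", {
  set.seed(41)
  ts <- matrix(rnorm(50 * 8), 50, 8)
  r <- pearson_matrix(ts)
  two_pass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(r[i, j], two_pass(ts[, i], ts[, j]), tolerance = 1e-12)
})

test_that("pearson_matrix rejects degenerate input", {
  expect_error(pearson_matrix(matrix(1:4, 2, 2)), "3 time points")
  ts <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(pearson_matrix(ts), "b")
})

test_that("binarize_at_sparsity keeps exactly round(S * npairs) edges", {
  set.seed(42)
  m <- pearson_matrix(matrix(rnorm(30 * 4), 30, 4))
  expect_equal(n_edges(binarize_at_sparsity(m, 0.5)), 3)  # round(0.5*6)
  m90 <- pearson_matrix(matrix(rnorm(240 * 90), 240, 90))
  for (s in sparsity_grid())
    expect_equal(n_edges(binarize_at_sparsity(m90, s)),
                 floor(s * 4005 + 0.5))
})

test_that("binarize ranks by |r| and breaks ties lexicographically", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.1
  m[2, 3] <- m[3, 2] <- 0.2
  net <- binarize_at_sparsity(m, 0.34)  # K = round(0.34*3) = 1
  expect_equal(edge_list(net), cbind(i = 1L, j = 2L), ignore_attr = TRUE)

  # two entries tied for the last slot: lower-indexed pair wins, both runs
  mt <- diag(4)
  mt[1, 2] <- mt[2, 1] <- 0.9
  mt[1, 3] <- mt[3, 1] <- 0.5
  mt[2, 3] <- mt[3, 2] <- -0.5   # same |r|, competes with (1,3)
  n1 <- binarize_at_sparsity(mt, 2 / 6)
  n2 <- binarize_at_sparsity(mt, 2 / 6)
  expect_identical(n1$adj, n2$adj)
  expect_equal(edge_list(n1)[2, ], c(i = 1L, j = 3L))

  # negative correlations rank by magnitude under the default mode
  mn <- diag(3)
  mn[1, 2] <- mn[2, 1] <- -0.95
  mn[1, 3] <- mn[3, 1] <- 0.4
  expect_equal(edge_list(binarize_at_sparsity(mn, 0.34)),
               cbind(i = 1L, j = 2L), ignore_attr = TRUE)
  expect_equal(edge_list(binarize_at_sparsity(mn, 0.34, mode = "positive")),
               cbind(i = 1L, j = 3L), ignore_attr = TRUE)
  expect_error(binarize_at_sparsity(mn, 0.01), "zero edges")
})

test_that("edge sets are nested across the sparsity grid", {
  set.seed(7)
  m <- pearson_matrix(matrix(rnorm(240 * 40), 240, 40))
  prev <- NULL
  for (s in sparsity_grid()) {
    e <- edge_list(binarize_at_sparsity(m, s))
    keys <- paste(e[, 1], e[, 2])
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("largest_component_size matches a contraction oracle", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(largest_component_size(binary_network(k5)), 5)
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- a[4, 5] <- a[5, 4] <- 1
  expect_equal(largest_component_size(binary_network(a)), 3)
  set.seed(11)
  for (i in 1:20) {
    adj <- random_adj(12, runif(1, 0.05, 0.3))
    expect_equal(largest_component_size(binary_network(adj)),
                 oracle_largest_component(adj))
  }
})

test_that("mean degree identity 2|E|/N holds after thresholding", {
  set.seed(3)
  m <- pearson_matrix(matrix(rnorm(240 * 90), 240, 90))
  net <- binarize_at_sparsity(m, 0.05)
  expect_equal(mean(degree_centrality(net)), 2 * n_edges(net) / 90)
  # at S = 0.05 the mean degree sits below the natural-log floor 2*ln(90)
  expect_lt(mean(degree_centrality(net)), 2 * log(90))
})

test_that("determine_regime returns the contiguous passing run", {
  set.seed(5)
  spec <- cohort_spec(n_per_group = c(ROT = 2, PT = 2, HC = 2),
                      effect_map = c(ROT = 1, PT = 1, HC = 1))
  co <- sample_cohort(spec)
  mats <- lapply(co$subjects, function(s) pearson_matrix(s$timeseries))
  cfg <- null_config(n_rand = 20, seed = 9)
  reg <- determine_regime(mats, grid = sparsity_grid(0.12, 0.16),
                          null_cfg = cfg)
  expect_s3_class(reg, "sparsity_regime")
  expect_true(all(diff(reg$grid) > 0))
  expect_true(all(reg$detail$pass[reg$detail$s %in% reg$grid]))
  # determinism under a fixed null seed
  reg2 <- determine_regime(mats, grid = sparsity_grid(0.12, 0.16),
                           null_cfg = cfg)
  expect_identical(reg$grid, reg2$grid)
  # the degree condition alone kills low thresholds for a single subject
  expect_error(
    determine_regime(mats[1], grid = c(0.05, 0.06), null_cfg = cfg),
    "no threshold")
})
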
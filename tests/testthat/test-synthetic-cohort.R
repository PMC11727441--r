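spec4 <- cohort_spec(n_per_group = c(ROT = 2, PT = 2, HC = 2),
                     n_rois = 4, t_len = 60,
                     module_sizes = c(a = 2, b = 2),
                     r_within = 0.6, r_between = 0.1)

test_that("block covariance matches its definition", {
  s0 <- cohort_spec(n_per_group = c(ROT = 1, PT = 1, HC = 1),
                    n_rois = 4, t_len = 60,
                    module_sizes = c(a = 2, b = 2),
                    r_within = 0, r_between = 0)
  expect_equal(unname(build_block_covariance(s0, "HC")), diag(4))

  sig <- build_block_covariance(spec4, "HC")
  expect_equal(unname(diag(sig)), rep(1, 4))
  expect_equal(sig[1, 2], 0.6)
  expect_equal(sig[3, 4], 0.6)
  expect_equal(sig[1, 3], 0.1)
  expect_equal(min(eigen(sig)$values), 0.4, tolerance = 1e-12)

  # planted effect scales within-block entries only
  s_eff <- cohort_spec(n_per_group = c(ROT = 1, PT = 1, HC = 1),
                       n_rois = 4, t_len = 60,
                       module_sizes = c(a = 2, b = 2),
                       r_within = 0.6, r_between = 0.1,
                       effect_map = c(ROT = 0.5, PT = 1, HC = 1))
  expect_equal(build_block_covariance(s_eff, "ROT")[1, 2], 0.30)
  expect_equal(build_block_covariance(s_eff, "HC")[1, 2], 0.60)
  expect_equal(build_block_covariance(s_eff, "ROT")[1, 3], 0.1)
})

test_that("invalid configurations are rejected at construction", {
  expect_error(cohort_spec(module_sizes = c(a = 50, b = 50)), "sum to n_rois")
  expect_error(cohort_spec(r_within = 0.2, r_between = 0.5), "r_between")
  expect_error(cohort_spec(r_within = 1.0), "r_within")
  expect_error(cohort_spec(effect_map = c(ROT = 0, PT = 1, HC = 1)))
})

test_that("identical spec and seed reproduce cohorts bit-identically", {
  c1 <- sample_cohort(spec4)
  c2 <- sample_cohort(spec4)
  expect_identical(c1$subjects, c2$subjects)
  # extending the cohort leaves existing subjects untouched
  spec_big <- cohort_spec(n_per_group = c(ROT = 3, PT = 2, HC = 2),
                          n_rois = 4, t_len = 60,
                          module_sizes = c(a = 2, b = 2),
                          r_within = 0.6, r_between = 0.1)
  c3 <- sample_cohort(spec_big)
  expect_identical(c1$subjects[[1]], c3$subjects[[1]])
  expect_identical(c1$subjects[[2]], c3$subjects[[2]])
})

test_that("sample correlation converges to the target covariance", {
  spec_long <- cohort_spec(n_per_group = c(ROT = 1, PT = 1, HC = 1),
                           n_rois = 20, t_len = 10000,
                           module_sizes = c(a = 10, b = 10),
                           r_within = 0.5, r_between = 0.15,
                           effect_map = c(ROT = 1, PT = 1, HC = 1),
                           seed = 123)
  co <- suppressWarnings(sample_cohort(spec_long))
  sub <- co$subjects[[which(vapply(co$subjects, `[[`, "", "group") == "HC")[1]]]
  r <- pearson_matrix(sub$timeseries)
  target <- build_block_covariance(spec_long, "HC")
  expect_lt(max(abs(unclass(r) - target)), 0.05)
})

test_that("lowering the effect factor lowers within-module correlation", {
  set.seed(200)
  spec_e <- cohort_spec(n_per_group = c(ROT = 5, PT = 5, HC = 5),
                        n_rois = 20, t_len = 240,
                        module_sizes = c(a = 10, b = 10),
                        r_within = 0.5, r_between = 0.1,
                        effect_map = c(ROT = 0.5, PT = 1, HC = 1),
                        seed = 77)
  co <- sample_cohort(spec_e)
  within_mean <- function(sub) {
    r <- pearson_matrix(sub$timeseries)
    idx <- 1:10
    mean(r[idx, idx][upper.tri(r[idx, idx])])
  }
  grp <- vapply(co$subjects, `[[`, "", "group")
  w <- vapply(co$subjects, within_mean, numeric(1))
  expect_lt(mean(w[grp == "ROT"]), mean(w[grp == "HC"]))
  expect_equal(mean(w[grp == "PT"]), mean(w[grp == "HC"]), tolerance = 0.1)
})

test_that("covariate model plants elevated hearing thresholds in tinnitus", {
  spec_c <- cohort_spec(n_per_group = c(ROT = 40, PT = 40, HC = 40),
                        n_rois = 4, t_len = 60,
                        module_sizes = c(a = 2, b = 2),
                        r_within = 0.3, r_between = 0.1, seed = 5)
  man <- cohort_manifest(sample_cohort(spec_c))
  expect_gt(mean(man$avg_ht[man$group == "ROT"]),
            mean(man$avg_ht[man$group == "HC"]))
  expect_gt(mean(man$ht_8k[man$group == "PT"]),
            mean(man$ht_8k[man$group == "HC"]))
  expect_true(all(is.na(man$duration[man$group == "HC"])))
  expect_true(all(man$duration[man$group == "ROT"] < 6))
  expect_true(all(man$duration[man$group == "PT"] >= 6))
  expect_true(all(man$group %in% c("ROT", "PT", "HC")))
})

test_that("short time series trigger the instability warning", {
  spec_s <- cohort_spec(n_per_group = c(ROT = 1, PT = 1, HC = 1),
                        n_rois = 30, t_len = 40,
                        module_sizes = c(a = 15, b = 15),
                        r_within = 0.3, r_between = 0.1)
  expect_warning(sample_cohort(spec_s), "unstable")
})

test_that("no ROI time series is constant", {
  co <- sample_cohort(spec4)
  for (s in co$subjects)
    expect_true(all(apply(s$timeseries, 2, sd) > 0))
})
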
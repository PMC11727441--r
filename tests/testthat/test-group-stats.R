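test_that("chi-square matches the closed form on 2x2 tables", {
  set.seed(90)
  for (i in 1:10) {
    tab <- matrix(sample(1:30, 4), 2, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi_square_test(tab)$statistic, closed, tolerance = 1e-12)
  }
})

test_that("chi-square invariances and degenerate cases", {
  tab <- rbind(c(6, 9, 12), c(10, 15, 20))  # identical row proportions
  expect_equal(chi_square_test(tab)$statistic, 0, tolerance = 1e-12)
  tab2 <- rbind(c(5, 9, 14), c(10, 8, 5))
  s <- chi_square_test(tab2)$statistic
  expect_equal(chi_square_test(tab2[, c(3, 1, 2)])$statistic, s)
  expect_equal(chi_square_test(tab2[c(2, 1), ])$statistic, s)
  expect_equal(chi_square_test(3 * tab2)$statistic, 3 * s, tolerance = 1e-12)
  expect_equal(chi_square_test(tab2)$df, 2)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("normality gate routes coarse-grid samples to the nonparametric branch", {
  set.seed(91)
  x <- rep(c(1, 2, 3), length.out = 60)  # 3-point lattice: non-normal
  g <- rep(c("a", "b"), each = 30)
  expect_equal(normality_gate(x, g)$route, "non-normal")
  y <- rnorm(60)
  gate <- normality_gate(y, g)
  expect_true(gate$route %in% c("normal", "non-normal"))
  expect_error(normality_gate(c(1, 2, rnorm(30)), rep(c("a", "b"), c(2, 30))),
               "fewer than 3")
})

test_that("the gate holds its nominal level on Gaussian samples", {
  set.seed(92)
  ok <- 0
  for (i in 1:100) {
    x <- rnorm(500)
    if (normality_gate(x, rep("g", 500))$route == "normal") ok <- ok + 1
  }
  expect_gte(ok, 90)
})

test_that("ANCOVA with inert covariates reduces to one-way ANOVA", {
  set.seed(93)
  n <- 60
  g <- rep(c("ROT", "PT", "HC"), each = n / 3)
  y <- rnorm(n) + (g == "ROT") * 0.8
  covs <- data.frame(age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.5),
                     avg_ht = rnorm(n, 20, 5), ht_8k = rnorm(n, 30, 8))
  # orthogonalize the covariates against group and response: they then
  # carry exactly zero information and the group sums of squares are
  # untouched -- the two F statistics differ only by the error df
  covs_orth <- as.data.frame(lapply(covs, function(z)
    residuals(lm(z ~ factor(g) + y))))
  f_ancova <- omnibus_and_pairwise(y, g, covariates = covs_orth,
                                   route = "parametric")
  f_anova <- omnibus_and_pairwise(y, g, route = "parametric")
  expect_equal(f_ancova$omnibus$statistic,
               f_anova$omnibus$statistic * (n - 7) / (n - 3),
               tolerance = 1e-8)
  expect_equal(length(f_ancova$pairwise$p), 3)
  # generic random covariates move the group F only modestly
  f_rand <- omnibus_and_pairwise(y, g, covariates = covs,
                                 route = "parametric")
  expect_lt(abs(log(f_rand$omnibus$statistic / f_anova$omnibus$statistic)),
            log(2))
})

test_that("LSD pairwise p-values agree with pooled t-tests sans covariates", {
  set.seed(94)
  g <- rep(c("a", "b", "c"), each = 15)
  y <- rnorm(45) + (g == "b") * 1
  gt <- omnibus_and_pairwise(y, g, route = "parametric")
  # LSD differs from a plain two-group t-test by using the 3-group pooled
  # variance; check directionality and ordering instead of equality
  pw <- gt$pairwise
  expect_true(all(pw$p >= 0 & pw$p <= 1))
  ab <- which(pw$group1 == "a" & pw$group2 == "b")
  ac <- which(pw$group1 == "a" & pw$group2 == "c")
  expect_lt(pw$p[ab], pw$p[ac])
  expect_identical(pw$p, pw$p_adj)  # LSD = uncorrected
})

test_that("Bonferroni correction multiplies and caps pairwise p", {
  set.seed(95)
  g <- rep(c("a", "b", "c"), each = 10)
  y <- rnorm(30)
  gt <- omnibus_and_pairwise(y, g, route = "parametric",
                             p_adjust = "bonferroni", family_size = 3)
  expect_equal(gt$pairwise$p_adj, pmin(gt$pairwise$p * 3, 1))
  expect_equal(pmin(0.02 * 3, 1), 0.06)
})

test_that("nonparametric route dispatches Kruskal-Wallis / Mann-Whitney", {
  set.seed(96)
  g <- rep(c("a", "b", "c"), each = 20)
  y <- rexp(60) + (g == "c") * 2      # skewed: fails the gate
  gt <- omnibus_and_pairwise(y, g, route = "auto")
  expect_equal(gt$route, "nonparametric")
  expect_match(gt$omnibus$method, "Kruskal")
  kw <- kruskal.test(y, factor(g))
  expect_equal(gt$omnibus$statistic, unname(kw$statistic))
  # with covariates the nonparametric route becomes rank ANCOVA
  covs <- data.frame(age = rnorm(60))
  gt2 <- omnibus_and_pairwise(y, g, covariates = covs, route = "nonparametric")
  expect_match(gt2$omnibus$method, "rank ANCOVA")
})

test_that("collinear covariates are rejected with the offending column", {
  set.seed(97)
  g <- rep(c("a", "b"), each = 10)
  y <- rnorm(20)
  covs <- data.frame(age = rnorm(20))
  covs$age2 <- 2 * covs$age
  expect_error(omnibus_and_pairwise(y, g, covariates = covs), "age2")
})

test_that("Spearman correlations and BH adjustment", {
  x <- 1:10
  res <- spearman_fdr(list(up = list(x = x, y = x^3),
                           down = list(x = x, y = rev(x^3))))
  expect_equal(res$rho, c(1, -1))
  # antisymmetry under reversal of x
  set.seed(98)
  a <- rnorm(20); b <- rnorm(20)
  r1 <- spearman_fdr(list(p = list(x = a, y = b)))$rho
  r3 <- spearman_fdr(list(p = list(x = -a, y = b)))$rho
  expect_equal(r3, -r1)
  # BH step-up on the textbook vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # degenerate member flagged
  resd <- spearman_fdr(list(flat = list(x = rep(1, 10), y = rnorm(10)),
                            ok = list(x = rnorm(10), y = rnorm(10))))
  expect_true(resd$degenerate[resd$pair == "flat"])
  expect_false(is.na(resd$q[resd$pair == "ok"]))
})

test_that("BH adjustment is monotone and stable on flat-adjusted vectors", {
  set.seed(99)
  p <- sort(runif(12))
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q) >= -1e-15))
  # a fully flattened BH output maps to itself
  flat <- p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH")
  expect_equal(p.adjust(flat, "BH"), flat)
})

test_that("group_stats_table produces one row per metric with pairwise p", {
  set.seed(100)
  g <- rep(c("ROT", "PT", "HC"), each = 10)
  dat <- data.frame(m1 = rnorm(30) - (g == "ROT"), m2 = rnorm(30))
  covs <- data.frame(age = rnorm(30, 45, 9))
  tab <- group_stats_table(dat, g, covariates = covs, route = "parametric")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("statistic", "p", "p_HC_vs_PT", "p_HC_vs_ROT",
                    "p_PT_vs_ROT") %in% names(tab)))
  expect_lt(tab$p[tab$variable == "m1"], 0.05)
})
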
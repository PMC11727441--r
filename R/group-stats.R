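#' Pearson chi-square test on a contingency table
#'
#' Chi-square of independence with expected counts from the product of
#' margins and no continuity correction, as used for sex and
#' side-of-tinnitus comparisons.
#'
#' @param table numeric matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @examples
#' chi_square_test(rbind(PT = c(5, 9, 14), ROT = c(10, 8, 5)))$statistic  # 5.552
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin: chi-square undefined")
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected)
}

#' Normality gate for group comparisons
#'
#' Shapiro-Wilk test per group at `alpha`; a variable is routed to the
#' parametric branch only if every group passes.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param alpha test level (default 0.05).
#' @return List with `route` (`"normal"` or `"non-normal"`) and the
#'   per-group Shapiro-Wilk p-values.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  p <- vapply(levels(groups), function(g) {
    x <- values[groups == g & !is.na(values)]
    if (length(x) < 3)
      stop("group ", g, " has fewer than 3 observations for normality testing")
    if (length(unique(x)) == 1) return(0)  # degenerate: certainly non-normal
    shapiro.test(x)$p.value
  }, numeric(1))
  list(route = if (all(p > alpha)) "normal" else "non-normal", p = p)
}

# pairwise LSD contrasts on the covariate-adjusted group means of a fitted
# linear model (uncorrected pairwise t-tests using the model's residual
# variance -- that is what LSD is)
.lsd_pairwise <- function(fit, group_var) {
  cf <- coef(fit)
  V <- vcov(fit)
  levs <- levels(fit$model[[group_var]])
  pairs <- utils::combn(levs, 2)
  df <- fit$df.residual
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    estimate = NA_real_, t = NA_real_, p = NA_real_)
  for (r in seq_len(ncol(pairs))) {
    ctr <- setNames(numeric(length(cf)), names(cf))
    t1 <- paste0(group_var, pairs[1, r])
    t2 <- paste0(group_var, pairs[2, r])
    if (t1 %in% names(ctr)) ctr[t1] <- 1
    if (t2 %in% names(ctr)) ctr[t2] <- -1
    est <- sum(ctr * cf)
    se <- sqrt(drop(t(ctr) %*% V %*% ctr))
    tval <- est / se
    out$estimate[r] <- est
    out$t[r] <- tval
    out$p[r] <- 2 * pt(-abs(tval), df)
  }
  out
}

#' Omnibus and pairwise group comparison of one variable
#'
#' Implements the study-style statistical routing. Parametric route:
#' one-way ANOVA (no covariates) or ANCOVA — the linear model
#' `y ~ covariates + group` with an F-test on the group factor added last —
#' followed by LSD post hoc contrasts (uncorrected pairwise t-tests on the
#' covariate-adjusted means, using the model's residual variance).
#' Non-parametric route: Kruskal-Wallis omnibus with Mann-Whitney U
#' pairwise tests; with covariates present the response is rank-transformed
#' and passed through the same ANCOVA machinery (rank ANCOVA).
#' `route = "auto"` applies the Shapiro-Wilk gate per group.
#'
#' @param values numeric response (e.g. one AUC metric).
#' @param groups group labels.
#' @param covariates optional data frame of covariates (e.g. age, sex,
#'   avg_ht, ht_8k); factors/characters are expanded to indicators.
#' @param route `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param p_adjust correction applied to the pairwise p-values: `"none"`
#'   (LSD) or `"bonferroni"`.
#' @param family_size number of simultaneous comparisons for the
#'   Bonferroni family (defaults to the number of pairwise tests).
#' @return One-row-per-test result of class `group_test`: `omnibus`
#'   (statistic, df, p, method) and data frame `pairwise`.
#' @export
omnibus_and_pairwise <- function(values, groups, covariates = NULL,
                                 route = c("auto", "parametric",
                                           "nonparametric"),
                                 p_adjust = c("none", "bonferroni"),
                                 family_size = NULL) {
  route <- match.arg(route)
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2)
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  if (route == "auto")
    route <- if (normality_gate(values, groups)$route == "normal")
      "parametric" else "nonparametric"

  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0
  if (has_cov) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop("covariates contain missing values")
    for (nm in names(covariates))
      if (!is.numeric(covariates[[nm]]))
        covariates[[nm]] <- as.numeric(factor(covariates[[nm]])) - 1
  }

  y <- if (route == "nonparametric" && has_cov) rank(values) else values
  method <- NULL

  if (route == "nonparametric" && !has_cov) {
    kw <- kruskal.test(values, groups)
    levs <- levels(groups)
    pairs <- utils::combn(levs, 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     estimate = NA_real_, t = NA_real_, p = NA_real_)
    for (r in seq_len(ncol(pairs))) {
      a <- values[groups == pairs[1, r]]
      b <- values[groups == pairs[2, r]]
      w <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      pw$estimate[r] <- median(a) - median(b)
      pw$p[r] <- w$p.value
    }
    omni <- list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value,
                 method = "Kruskal-Wallis / Mann-Whitney")
  } else {
    dat <- data.frame(.y = y, .group = groups)
    if (has_cov) {
      dat <- cbind(dat, covariates)
      mm <- stats::model.matrix(~ ., data = covariates)
      qrm <- qr(mm)
      if (qrm$rank < ncol(mm)) {
        bad <- colnames(mm)[!(seq_len(ncol(mm)) %in% qrm$pivot[seq_len(qrm$rank)])]
        stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
      }
      fml <- stats::as.formula(paste(
        ".y ~", paste(names(covariates), collapse = " + "), "+ .group"))
    } else {
      fml <- .y ~ .group
    }
    fit <- lm(fml, data = dat)
    if (fit$df.residual < 1)
      stop("insufficient residual degrees of freedom (",
           length(values), " observations for ",
           length(coef(fit)), " model parameters)")
    an <- anova(fit)
    row <- which(rownames(an) == ".group")
    omni <- list(statistic = an$`F value`[row],
                 df = c(an$Df[row], fit$df.residual),
                 p = an$`Pr(>F)`[row],
                 method = paste0(
                   if (route == "nonparametric") "rank " else "",
                   if (has_cov) "ANCOVA" else "ANOVA", " / LSD"))
    pw <- .lsd_pairwise(fit, ".group")
  }
  if (p_adjust == "bonferroni") {
    m <- if (is.null(family_size)) nrow(pw) else family_size
    pw$p_adj <- pmin(pw$p * m, 1)
  } else {
    pw$p_adj <- pw$p
  }
  structure(list(omnibus = omni, pairwise = pw, route = route,
                 correction = p_adjust),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.3f, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Spearman correlations with FDR correction
#'
#' Rank correlation (average ranks on ties) for a set of variable pairs,
#' with Benjamini-Hochberg adjustment across all tested pairs. Pairs with a
#' constant member are flagged and excluded from the adjustment.
#'
#' @param pairs named list; each element a list/data frame with numeric
#'   `x` and `y` of equal length (pairs with missing values are dropped
#'   observation-wise).
#' @return Data frame: `pair`, `n`, `rho`, `p`, `q` (BH-adjusted), and
#'   logical `degenerate`.
#' @export
spearman_fdr <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1)
  if (is.null(names(pairs)))
    names(pairs) <- paste0("pair", seq_along(pairs))
  rows <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]]$x
    y <- pairs[[nm]]$y
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4) stop("pair ", nm, ": fewer than 4 complete observations")
    if (length(unique(x)) == 1 || length(unique(y)) == 1)
      return(data.frame(pair = nm, n = length(x), rho = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(pair = nm, n = length(x), rho = unname(ct$estimate),
               p = ct$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !out$degenerate
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out[, c("pair", "n", "rho", "p", "q", "degenerate")]
}

#' Group comparison table over many variables
#'
#' Applies [omnibus_and_pairwise()] to each column of a wide table of
#' per-subject values (e.g. AUC metrics), producing one row per variable in
#' the shape of the study's group-comparison tables: group summaries,
#' omnibus statistic and p, and pairwise p-values after the requested
#' correction.
#'
#' @param data data frame of per-subject variables (columns = metrics).
#' @param groups group label per row of `data`.
#' @param covariates optional covariate data frame (ANCOVA route).
#' @param route,p_adjust,family_size passed to [omnibus_and_pairwise()].
#' @return Data frame, one row per variable, with columns
#'   `mean_<group>`, `sd_<group>`, `statistic`, `p`, and
#'   `p_<g1>_vs_<g2>` for each group pair.
#' @export
group_stats_table <- function(data, groups, covariates = NULL,
                              route = "auto", p_adjust = "none",
                              family_size = NULL) {
  data <- as.data.frame(data)
  groups <- factor(groups)
  rows <- lapply(names(data), function(v) {
    gt <- omnibus_and_pairwise(data[[v]], groups, covariates = covariates,
                               route = route, p_adjust = p_adjust,
                               family_size = family_size)
    sums <- unlist(lapply(levels(groups), function(g) {
      x <- data[[v]][groups == g]
      setNames(c(mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)),
               paste0(c("mean_", "sd_"), g))
    }))
    pw <- setNames(gt$pairwise$p_adj,
                   paste0("p_", gt$pairwise$group1, "_vs_", gt$pairwise$group2))
    out <- data.frame(variable = v, t(sums), statistic = gt$omnibus$statistic,
                      p = gt$omnibus$p, t(pw), method = gt$omnibus$method,
                      check.names = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
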
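#' Integrate a metric curve across the sparsity grid (AUC)
#'
#' Collapses a metric's values over the threshold grid into a single
#' threshold-independent scalar, the area under the curve, by the composite
#' trapezoidal rule over non-missing grid points (piecewise-linear
#' quadrature; a left-rectangle rule is available for sensitivity
#' analysis). Units are metric-units x sparsity-units.
#'
#' @param values metric value at each threshold; `NA` entries are dropped.
#' @param thresholds strictly ascending grid with constant step.
#' @param method `"trapezoid"` (default) or `"left"` rectangle rule.
#' @return Scalar AUC.
#' @examples
#' metric_auc(rep(2, 14), sparsity_grid())  # 2 * 0.13 = 0.26
#' @export
metric_auc <- function(values, thresholds, method = c("trapezoid", "left")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(thresholds))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  steps <- diff(thresholds)
  if (length(steps) > 1 && max(abs(steps - steps[1])) > 1e-9)
    stop("threshold grid must have a constant step")
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop("AUC requires at least 2 non-missing points (got ", sum(ok), ")")
  x <- thresholds[ok]
  y <- values[ok]
  if (method == "trapezoid") {
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  } else {
    sum(diff(x) * head(y, -1))
  }
}

# AUC per group of rows of a long table value ~ threshold, keyed by `by`
# columns; panels with < 2 usable points are skipped with a message.
.auc_table <- function(df, value_col, by, thresholds, method = "trapezoid") {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  parts <- split(df, key)
  rows <- lapply(parts, function(p) {
    p <- p[order(p$s), ]
    ok <- !is.na(p[[value_col]])
    if (sum(ok) < 2) {
      message("AUC panel skipped (", paste(unlist(p[1, by]), collapse = "/"),
              "): fewer than 2 usable points")
      return(NULL)
    }
    out <- p[1, by, drop = FALSE]
    out$auc <- metric_auc(p[[value_col]], p$s, method = method)
    out
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(res) <- NULL
  res
}
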
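#' Anatomical module labels of the 90-ROI parcellation
#'
#' The six canonical modules over which modular connectivity is summarized.
#'
#' @return Character vector of the six module names.
#' @export
module_labels <- function() {
  c("frontal", "prefrontal", "parietal", "temporal", "occipital", "subcortical")
}

#' Module partition of network nodes
#'
#' Assigns every ROI to exactly one module. The shipped default for the
#' 90-ROI anatomical atlas uses the six modules of [module_labels()]; any
#' partition with >= 2 modules and no singleton module is accepted, so the
#' machinery also works on small constructed graphs.
#'
#' @param modules character/factor vector of module labels, one per ROI.
#' @param roi_names optional ROI names (defaults to names of `modules`).
#' @return Object of class `module_partition`: factor `modules` named by
#'   ROI, plus `sizes`.
#' @export
module_partition <- function(modules, roi_names = NULL) {
  if (is.null(roi_names)) roi_names <- names(modules)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_along(modules))
  stopifnot(length(roi_names) == length(modules), !anyDuplicated(roi_names))
  f <- factor(as.character(modules))
  if (nlevels(f) < 2) stop("a partition needs at least 2 modules")
  sizes <- table(f)
  if (any(sizes < 2))
    stop("singleton module(s) not allowed: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  names(f) <- roi_names
  structure(list(modules = f, sizes = as.integer(sizes),
                 labels = levels(f)), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:",
      paste(sprintf("%s(%d)", x$labels, x$sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Default six-module partition of the 90-ROI atlas
#'
#' Reads the partition table shipped with the package (a documented
#' reconstruction from the atlas region nomenclature: frontal 8,
#' prefrontal 24, parietal 16, temporal 20, occipital 12, subcortical 10).
#'
#' @return A [module_partition()] covering 90 ROIs.
#' @export
default_partition <- function() {
  path <- system.file("extdata", "aal90_modules.tsv", package = "fcnet")
  read_partition(path)
}

.match_partition <- function(net, part) {
  stopifnot(inherits(net, "binary_network"), inherits(part, "module_partition"))
  if (length(part$modules) != net$n_nodes)
    stop("partition covers ", length(part$modules), " ROIs but network has ",
         net$n_nodes, " nodes")
  if (!is.null(names(part$modules)) &&
      all(net$node_names %in% names(part$modules))) {
    part$modules[net$node_names]
  } else {
    part$modules
  }
}

#' Intra-module connection strength
#'
#' Edge density within one module: realized edges with both endpoints in
#' the module divided by the module's possible pairs.
#'
#' @param net a [binary_network()].
#' @param part a [module_partition()].
#' @param m module label.
#' @return Density in \[0, 1\].
#' @export
intra_module_strength <- function(net, part, m) {
  mods <- .match_partition(net, part)
  if (!m %in% levels(mods)) stop("unknown module: ", m)
  idx <- which(mods == m)
  nm <- length(idx)
  if (nm < 2) stop("module ", m, " has fewer than 2 ROIs")
  sum(net$adj[idx, idx]) / 2 / (nm * (nm - 1) / 2)
}

#' Inter-module connection strength
#'
#' Edge density between two modules: realized cross edges divided by
#' |m1| x |m2|.
#'
#' @inheritParams intra_module_strength
#' @param m1,m2 distinct module labels.
#' @return Density in \[0, 1\].
#' @export
inter_module_strength <- function(net, part, m1, m2) {
  if (identical(m1, m2)) stop("m1 and m2 must differ")
  mods <- .match_partition(net, part)
  if (!all(c(m1, m2) %in% levels(mods)))
    stop("unknown module label among: ", m1, ", ", m2)
  i1 <- which(mods == m1)
  i2 <- which(mods == m2)
  sum(net$adj[i1, i2]) / (length(i1) * length(i2))
}

#' All intra- and inter-module connection strengths of one network
#'
#' For a six-module partition this yields the canonical 21 measures
#' (6 intra + 15 inter) per network. Raw edge counts are emitted alongside
#' densities for audit, since "mean number of connections" admits both
#' readings.
#'
#' @inheritParams intra_module_strength
#' @return Data frame with columns `measure` (e.g. `"frontal"` or
#'   `"frontal-parietal"`), `type`, `density`, `count`, `possible`.
#' @export
module_connectivity <- function(net, part) {
  mods <- .match_partition(net, part)
  labs <- levels(mods)
  idx <- lapply(labs, function(l) which(mods == l))
  names(idx) <- labs
  rows <- list()
  for (l in labs) {
    i <- idx[[l]]
    cnt <- sum(net$adj[i, i]) / 2
    poss <- length(i) * (length(i) - 1) / 2
    rows[[length(rows) + 1]] <- data.frame(
      measure = l, type = "intra", density = cnt / poss,
      count = cnt, possible = poss)
  }
  if (length(labs) > 1) {
    for (a in seq_len(length(labs) - 1)) {
      for (b in (a + 1):length(labs)) {
        i <- idx[[labs[a]]]; j <- idx[[labs[b]]]
        cnt <- sum(net$adj[i, j])
        poss <- length(i) * length(j)
        rows[[length(rows) + 1]] <- data.frame(
          measure = paste0(labs[a], "-", labs[b]), type = "inter",
          density = cnt / poss, count = cnt, possible = poss)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
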
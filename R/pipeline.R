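# lightweight config fingerprint for output metadata (not cryptographic)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full connectome analysis pipeline on a cohort
#'
#' Executes, per subject: Pearson connectivity matrix, binarization at
#' every threshold of the sparsity grid, global (and optionally nodal)
#' topological metrics, optional small-world normalization against
#' degree-preserving null ensembles, optional modular connectivity; then
#' integrates every metric curve across the grid (AUC) and, optionally,
#' compares groups by covariate-adjusted ANCOVA with LSD post hoc tests
#' (Bonferroni correction for the nodal and module families).
#'
#' The run is deterministic for a fixed cohort and `seed`: null-ensemble
#' substreams are derived from `seed`, subject index and threshold index.
#'
#' @param cohort an `fc_cohort` (from [sample_cohort()] or [read_cohort()]).
#' @param grid sparsity thresholds (default [sparsity_grid()]).
#' @param mode edge-ranking mode for [binarize_at_sparsity()].
#' @param nodal compute nodal metrics (DC, NCp, NLp, Ne, Nle, BC).
#' @param small_world compute gamma/lambda/sigma per subject and threshold.
#' @param modules compute intra/inter-module connection strengths.
#' @param stats run the group-statistics layer on the AUC tables.
#' @param null_cfg a [null_config()] for the small-world ensembles.
#' @param partition module partition; defaults to the cohort's own.
#' @param covariate_names manifest columns used as ANCOVA covariates.
#' @param seed integer seed for the null ensembles.
#' @return Object of class `fc_pipeline` with elements `global`, `nodal`,
#'   `module` (long per-threshold tables), `auc_global`, `auc_nodal`,
#'   `auc_module`, `manifest`, statistics tables `stats_global`,
#'   `stats_nodal`, `stats_module` (when `stats = TRUE`), and `config`.
#' @export
run_pipeline <- function(cohort, grid = sparsity_grid(),
                         mode = c("absolute", "positive"),
                         nodal = TRUE, small_world = TRUE, modules = TRUE,
                         stats = TRUE,
                         null_cfg = null_config(),
                         partition = NULL,
                         covariate_names = c("age", "sex", "avg_ht", "ht_8k"),
                         seed = 1L) {
  stopifnot(inherits(cohort, "fc_cohort"), length(grid) >= 2)
  mode <- match.arg(mode)
  if (is.null(partition)) partition <- cohort$partition
  if (modules && is.null(partition))
    stop("modular analysis requested but no partition available")
  man <- cohort_manifest(cohort)

  glob_rows <- vector("list", 0)
  nodal_rows <- vector("list", 0)
  mod_rows <- vector("list", 0)

  for (si in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[si]]
    m <- pearson_matrix(sub$timeseries)
    for (ti in seq_along(grid)) {
      net <- binarize_at_sparsity(m, grid[ti], mode = mode)
      gm <- network_metrics(net, betweenness = nodal, local = TRUE)
      row <- data.frame(subject_id = sub$subject_id, group = sub$group,
                        s = grid[ti], cp = gm$cp, lp = gm$lp,
                        eglob = gm$eglob, eloc = gm$eloc,
                        largest_component = largest_component_size(net),
                        unreachable_pairs = gm$unreachable_pairs)
      if (small_world) {
        cfg <- null_config(
          n_rand = null_cfg$n_rand,
          swaps_per_edge = null_cfg$swaps_per_edge,
          seed = (seed + 131L * si + 7919L * ti) %% .Machine$integer.max)
        sw <- small_world(net, cfg)
        row$gamma <- sw$gamma
        row$lambda <- sw$lambda
        row$sigma <- sw$sigma
      }
      glob_rows[[length(glob_rows) + 1]] <- row
      if (nodal) {
        nd <- gm$nodal
        nd$subject_id <- sub$subject_id
        nd$group <- sub$group
        nd$s <- grid[ti]
        nodal_rows[[length(nodal_rows) + 1]] <- nd
      }
      if (modules) {
        mc <- module_connectivity(net, partition)
        mc$subject_id <- sub$subject_id
        mc$group <- sub$group
        mc$s <- grid[ti]
        mod_rows[[length(mod_rows) + 1]] <- mc
      }
    }
  }
  glob <- do.call(rbind, glob_rows)
  nodal_tab <- if (nodal) do.call(rbind, nodal_rows) else NULL
  mod_tab <- if (modules) do.call(rbind, mod_rows) else NULL

  # AUC integration across the grid
  gmetrics <- intersect(c("cp", "lp", "eglob", "eloc",
                          "gamma", "lambda", "sigma"), names(glob))
  auc_global <- NULL
  for (mt in gmetrics) {
    a <- .auc_table(glob, mt, c("subject_id", "group"), grid)
    names(a)[names(a) == "auc"] <- paste0("a_", mt)
    auc_global <- if (is.null(auc_global)) a else
      merge(auc_global, a, by = c("subject_id", "group"))
  }
  auc_nodal <- NULL
  if (nodal) {
    parts <- lapply(c("dc", "ncp", "nlp", "ne", "nle", "bc"), function(mt) {
      a <- .auc_table(nodal_tab, mt, c("subject_id", "group", "node"), grid)
      a$metric <- paste0("a_", mt)
      a
    })
    auc_nodal <- do.call(rbind, parts)
  }
  auc_module <- if (modules)
    .auc_table(mod_tab, "density", c("subject_id", "group", "measure"), grid)
  else NULL

  res <- list(global = glob, nodal = nodal_tab, module = mod_tab,
              auc_global = auc_global, auc_nodal = auc_nodal,
              auc_module = auc_module, manifest = man, grid = grid,
              partition = partition)
  if (stats) {
    covs <- man[, intersect(covariate_names, names(man)), drop = FALSE]
    groups <- auc_global$group
    ord <- match(auc_global$subject_id, man$subject_id)
    covs <- covs[ord, , drop = FALSE]
    metric_cols <- setdiff(names(auc_global), c("subject_id", "group"))
    res$stats_global <- group_stats_table(
      auc_global[metric_cols], groups, covariates = covs,
      route = "parametric", p_adjust = "none")
    if (nodal) res$stats_nodal <- .stats_long(auc_nodal, man, covs = covs,
                                             key = "node")
    if (modules) res$stats_module <- .stats_long(
      auc_module, man, covs = covs, key = "measure",
      family_size = length(unique(auc_module$measure)))
  }
  cfg <- list(grid = grid, mode = mode, nodal = nodal,
              small_world = small_world, modules = modules,
              null_cfg = unclass(null_cfg), seed = seed,
              covariates = covariate_names)
  res$config <- c(cfg, hash = .config_hash(cfg))
  class(res) <- "fc_pipeline"
  res
}

# per-key ANCOVA over a long AUC table; Bonferroni across the key family
.stats_long <- function(auc_long, man, covs, key,
                        family_size = NULL) {
  has_metric <- "metric" %in% names(auc_long)
  split_keys <- if (has_metric) c(key, "metric") else key
  parts <- split(auc_long, auc_long[split_keys], drop = TRUE)
  if (is.null(family_size)) family_size <- length(unique(auc_long[[key]]))
  rows <- lapply(parts, function(p) {
    ord <- match(p$subject_id, man$subject_id)
    gt <- try(omnibus_and_pairwise(
      p$auc, p$group, covariates = covs[ord, , drop = FALSE],
      route = "parametric", p_adjust = "bonferroni",
      family_size = family_size), silent = TRUE)
    if (inherits(gt, "try-error")) return(NULL)
    out <- data.frame(key = p[[key]][1], statistic = gt$omnibus$statistic,
                      p = gt$omnibus$p)
    if (has_metric) out$metric <- p$metric[1]
    pw <- setNames(gt$pairwise$p_adj,
                   paste0("p_", gt$pairwise$group1, "_vs_",
                          gt$pairwise$group2))
    cbind(out, t(pw))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  names(out)[names(out) == "key"] <- key
  rownames(out) <- NULL
  out
}

#' @export
print.fc_pipeline <- function(x, ...) {
  cat(sprintf(
    "fc_pipeline: %d subjects x %d thresholds (%.2f-%.2f)\n",
    length(unique(x$global$subject_id)), length(x$grid),
    min(x$grid), max(x$grid)))
  cat("  tables:", paste(names(x)[!vapply(x, is.null, logical(1))],
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fc_pipeline <- function(object, ...) {
  cat("Global AUC metrics by group (mean):\n")
  mcols <- setdiff(names(object$auc_global), c("subject_id", "group"))
  agg <- aggregate(object$auc_global[mcols],
                   by = list(group = object$auc_global$group), mean)
  print(agg, digits = 4)
  if (!is.null(object$stats_global)) {
    cat("\nGroup comparison (covariate-adjusted):\n")
    print(object$stats_global[, c("variable", "statistic", "p")],
          digits = 4)
  }
  invisible(object)
}

#' Write pipeline outputs as CSV tables
#'
#' Each table carries a metadata header (config hash, seed, package
#' version) as comment lines so runs can be audited and reproduced.
#'
#' @param result an `fc_pipeline`.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "fc_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf(
    "# fcnet %s | config %s | seed %s",
    as.character(utils::packageVersion("fcnet")),
    result$config$hash, result$config$seed)
  tabs <- c("global", "nodal", "module", "auc_global", "auc_nodal",
            "auc_module", "stats_global", "stats_nodal", "stats_module")
  written <- character(0)
  for (tb in tabs) {
    if (is.null(result[[tb]])) next
    p <- file.path(dir, paste0(tb, ".csv"))
    con <- file(p, "w")
    writeLines(hdr, con)
    write.csv(result[[tb]], con, row.names = FALSE)
    close(con)
    written <- c(written, p)
  }
  invisible(written)
}
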
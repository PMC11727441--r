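#' Write a cohort to plain-text files
#'
#' Per-subject time-series TSVs (T rows x N ROI columns, header = ROI
#' names) under `<dir>/timeseries/`, a cohort manifest CSV, and the
#' node/module partition TSV — the on-disk interchange format consumed by
#' the readers below.
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in cohort$subjects) {
    p <- file.path(ts_dir, paste0(s$subject_id, ".tsv"))
    write.table(s$timeseries, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(cohort_manifest(cohort), mp, row.names = FALSE)
  pp <- file.path(dir, "partition.tsv")
  write.table(data.frame(roi = names(cohort$partition$modules),
                         module = as.character(cohort$partition$modules)),
              pp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, mp, pp))
}

#' Read an ROI time-series matrix
#'
#' Tab-separated, UTF-8, header row of ROI names, T rows x N numeric
#' columns. Any non-numeric cell is reported with its row and column.
#'
#' @param path file path.
#' @param roi_names optional expected ROI names; a mismatch in count or
#'   names is an error.
#' @return Numeric T x N matrix with ROI column names.
#' @export
read_timeseries <- function(path, roi_names = NULL) {
  raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  mat <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw))))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(raw))
  colnames(mat) <- names(raw)
  if (anyNA(mat)) {
    bad <- which(is.na(mat) & !is.na(raw), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(mat), arr.ind = TRUE)
    stop(sprintf("non-numeric value in %s at row %d, column '%s'",
                 basename(path), bad[1, 1], colnames(mat)[bad[1, 2]]))
  }
  if (!is.null(roi_names)) {
    if (ncol(mat) != length(roi_names))
      stop(sprintf("%s has %d columns; %d ROIs expected",
                   basename(path), ncol(mat), length(roi_names)))
    if (!identical(colnames(mat), roi_names))
      stop(basename(path), ": ROI column names do not match the node table")
  }
  mat
}

#' Read a cohort manifest
#'
#' Comma-separated; must contain `subject_id` and `group` columns, group
#' labels drawn from ROT / PT / HC, subject ids unique.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(man)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject ids in manifest: ",
         paste(unique(man$subject_id[duplicated(man$subject_id)]),
               collapse = ", "))
  bad <- setdiff(unique(man$group), c("ROT", "PT", "HC"))
  if (length(bad))
    stop("unknown group label(s) in manifest: ", paste(bad, collapse = ", "))
  man
}

#' Read a ROI-to-module partition table
#'
#' Tab-separated with columns `roi` and `module`. By default module labels
#' are validated against the six canonical anatomical modules; pass
#' `labels = NULL` to accept any partition.
#'
#' @param path file path.
#' @param labels allowed module labels, or `NULL` to skip the check.
#' @return A [module_partition()].
#' @export
read_partition <- function(path, labels = module_labels()) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("roi", "module") %in% names(tab)))
    stop("partition table must contain columns: roi, module")
  if (!is.null(labels)) {
    bad <- setdiff(unique(tab$module), labels)
    if (length(bad))
      stop("unknown module label(s): ", paste(bad, collapse = ", "))
  }
  module_partition(tab$module, roi_names = tab$roi)
}

#' Read a node table
#'
#' Tab-separated with columns `node`, `x`, `y`, `z` (MNI mm) and any
#' additional annotation columns; node names must be unique and
#' coordinates finite. The package ships a fixture of tested nodes in MNI
#' space under `extdata/tested_nodes_mni.tsv`.
#'
#' @param path file path; default the shipped fixture.
#' @return Data frame.
#' @export
read_node_table <- function(path = system.file("extdata",
                                               "tested_nodes_mni.tsv",
                                               package = "fcnet")) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
  need <- c("node", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("node table must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$node))
    stop("duplicate node names in node table")
  if (!all(is.finite(as.matrix(tab[, c("x", "y", "z")]))))
    stop("non-finite MNI coordinates in node table")
  tab
}

#' Read a cohort back from disk
#'
#' Inverse of [write_cohort()]: reads the manifest, the partition and all
#' per-subject time series, validating dimensions against the partition.
#'
#' @param dir directory written by [write_cohort()].
#' @return Object of class `fc_cohort` (without a generator spec).
#' @export
read_cohort <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  part <- read_partition(file.path(dir, "partition.tsv"), labels = NULL)
  roi <- names(part$modules)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    ts <- read_timeseries(
      file.path(dir, "timeseries", paste0(man$subject_id[i], ".tsv")),
      roi_names = roi)
    c(list(timeseries = ts), as.list(man[i, ]))
  })
  structure(list(subjects = subjects, spec = NULL, partition = part,
                 roi_names = roi),
            class = "fc_cohort")
}
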
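#' Specification of a synthetic resting-state cohort
#'
#' Defines the study conditions for simulated cohorts: three groups of
#' subjects (ROT = recent-onset tinnitus, PT = persistent tinnitus,
#' HC = healthy controls), each subject a T x N matrix of BOLD-like ROI
#' time series drawn from a zero-mean multivariate normal whose covariance
#' has a block-modular structure over the anatomical modules. A planted
#' segregation deficit multiplies the within-module correlation of selected
#' groups by `effect_map` (default: factor 0.5 in ROT), and clinical
#' covariates get group-wise offsets (tinnitus groups have elevated hearing
#' thresholds).
#'
#' @param n_per_group named counts for ROT, PT, HC (default 25 each).
#' @param n_rois node count (default 90).
#' @param t_len time points per subject (default 240).
#' @param module_sizes named module sizes summing to `n_rois`; the default
#'   mirrors the six-module anatomical parcellation.
#' @param r_within target within-module correlation in \[0, 1).
#' @param r_between target between-module correlation in \[0, r_within\].
#' @param effect_map named per-group factor in (0, 1\] multiplying
#'   `r_within` (the planted within-module deficit).
#' @param covariate_model nested list `group -> covariate -> c(mean, sd)`
#'   for age, avg_ht (dB HL), ht_8k (dB HL); see default.
#' @param sex_prob named per-group probability of male.
#' @param smooth_window odd moving-average window for optional temporal
#'   low-pass smoothing (band-limit emulation); 1 = off (default).
#'   Correlation targets refer to the pre-smoothing process.
#' @param seed integer RNG seed; subject i uses substream `seed + i` so a
#'   cohort can be extended without reshuffling existing subjects.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(ROT = 25, PT = 25, HC = 25),
                        n_rois = 90, t_len = 240,
                        module_sizes = c(frontal = 8, prefrontal = 24,
                                         parietal = 16, temporal = 20,
                                         occipital = 12, subcortical = 10),
                        r_within = 0.4, r_between = 0.1,
                        effect_map = c(ROT = 0.5, PT = 1, HC = 1),
                        covariate_model = default_covariate_model(),
                        sex_prob = c(ROT = 0.5, PT = 0.5, HC = 0.5),
                        smooth_window = 1,
                        seed = 1L) {
  groups <- c("ROT", "PT", "HC")
  stopifnot(all(groups %in% names(n_per_group)),
            all(n_per_group[groups] >= 1),
            n_rois >= 2, t_len >= 3,
            all(module_sizes >= 1),
            all(groups %in% names(effect_map)),
            all(effect_map[groups] > 0 & effect_map[groups] <= 1),
            all(groups %in% names(sex_prob)),
            smooth_window >= 1, smooth_window %% 2 == 1)
  if (sum(module_sizes) != n_rois)
    stop("module_sizes must sum to n_rois (", sum(module_sizes), " != ",
         n_rois, ")")
  if (!(r_between >= 0 && r_between <= r_within && r_within < 1))
    stop("need 0 <= r_between <= r_within < 1")
  if (is.null(names(module_sizes)))
    names(module_sizes) <- paste0("module", seq_along(module_sizes))
  spec <- structure(
    list(n_per_group = n_per_group[groups], n_rois = n_rois, t_len = t_len,
         module_sizes = module_sizes, r_within = r_within,
         r_between = r_between, effect_map = effect_map[groups],
         covariate_model = covariate_model, sex_prob = sex_prob[groups],
         smooth_window = smooth_window, seed = as.integer(seed)),
    class = "cohort_spec")
  # invariant: every group covariance is PSD, checked at construction
  for (g in groups) build_block_covariance(spec, g)
  spec
}

#' Default covariate model
#'
#' Group-wise means and SDs for age (years) and hearing thresholds (dB HL).
#' Tinnitus groups get elevated thresholds, mirroring the direction seen in
#' tinnitus cohorts without copying any study's values; ages match across
#' groups.
#'
#' @return Nested list `group -> covariate -> c(mean, sd)`.
#' @export
default_covariate_model <- function() {
  list(
    ROT = list(age = c(45, 10), avg_ht = c(25, 8), ht_8k = c(40, 12)),
    PT  = list(age = c(45, 10), avg_ht = c(26, 8), ht_8k = c(42, 12)),
    HC  = list(age = c(45, 10), avg_ht = c(15, 5), ht_8k = c(20, 8)))
}

#' Block-modular covariance matrix for one group
#'
#' Unit-diagonal covariance with entries `r_within * effect_map[group]`
#' inside each module block and `r_between` across blocks; the statistical
#' stand-in for modular brain covariance that the generator samples from.
#'
#' @param spec a [cohort_spec()].
#' @param group group label (`"ROT"`, `"PT"`, `"HC"`).
#' @return N x N positive semi-definite matrix with ROI dimnames.
#' @examples
#' s <- cohort_spec(n_rois = 4, module_sizes = c(a = 2, b = 2),
#'                  r_within = 0.6, r_between = 0.1)
#' min(eigen(build_block_covariance(s, "HC"))$values)  # 0.4
#' @export
build_block_covariance <- function(spec, group) {
  stopifnot(inherits(spec, "cohort_spec"), group %in% names(spec$effect_map))
  rw <- spec$r_within * spec$effect_map[[group]]
  sigma <- matrix(spec$r_between, spec$n_rois, spec$n_rois)
  mod <- rep(names(spec$module_sizes), spec$module_sizes)
  for (m in names(spec$module_sizes)) {
    idx <- which(mod == m)
    sigma[idx, idx] <- rw
  }
  diag(sigma) <- 1
  nm <- roi_names_for(spec)
  dimnames(sigma) <- list(nm, nm)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf(
      "covariance for group %s is not positive semi-definite (smallest eigenvalue %.4g)",
      group, min(ev)))
  sigma
}

#' ROI names implied by a cohort spec
#'
#' Module-blocked names of the form `<module>_<k>`.
#'
#' @param spec a [cohort_spec()].
#' @return Character vector of length `n_rois`.
#' @export
roi_names_for <- function(spec) {
  unlist(lapply(names(spec$module_sizes), function(m)
    sprintf("%s_%02d", m, seq_len(spec$module_sizes[[m]]))),
    use.names = FALSE)
}

#' Module partition implied by a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return A [module_partition()] matching [roi_names_for()].
#' @export
spec_partition <- function(spec) {
  module_partition(rep(names(spec$module_sizes), spec$module_sizes),
                   roi_names = roi_names_for(spec))
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Sample a synthetic cohort
#'
#' Draws every subject's time series from the group's block-modular
#' multivariate normal (via a Cholesky factor), plus demographic and
#' clinical covariates from the covariate model. Subject i is generated
#' under seed `spec$seed + i`, so identical spec + seed reproduces the
#' cohort bit-identically and extending `n_per_group` leaves earlier
#' subjects unchanged.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `fc_cohort`: list with `subjects` (list of
#'   subject records), `spec`, `partition`, `roi_names`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$t_len < 2 * spec$n_rois)
    warning("t_len < 2 * n_rois: correlation estimates will be unstable")
  nm <- roi_names_for(spec)
  chols <- lapply(names(spec$n_per_group), function(g)
    chol(build_block_covariance(spec, g)))
  names(chols) <- names(spec$n_per_group)

  subjects <- list()
  i_global <- 0L
  for (g in names(spec$n_per_group)) {
    cm <- spec$covariate_model[[g]]
    for (k in seq_len(spec$n_per_group[[g]])) {
      i_global <- i_global + 1L
      set.seed((spec$seed + i_global) %% .Machine$integer.max)
      age <- .rtrunc_norm(1, cm$age[1], cm$age[2], 18, 80)
      sex <- if (rbinom(1, 1, spec$sex_prob[[g]]) == 1) "male" else "female"
      avg_ht <- .rtrunc_norm(1, cm$avg_ht[1], cm$avg_ht[2], 0, 120)
      ht_8k <- .rtrunc_norm(1, cm$ht_8k[1], cm$ht_8k[2], 0, 120)
      tinnitus <- g %in% c("ROT", "PT")
      duration <- if (!tinnitus) NA_real_
                  else if (g == "ROT") runif(1, 1, 6) else runif(1, 6, 60)
      pm <- if (tinnitus) exp(runif(1, log(500), log(8000))) else NA_real_
      lm <- if (tinnitus) .rtrunc_norm(1, 30, 10, 0, 100) else NA_real_
      tfi <- if (tinnitus) {
        sub <- .rtrunc_norm(8, 4, 2, 0, 10)
        names(sub) <- paste0("tfi_", c("i", "sc", "c", "sl", "a", "r", "q", "e"))
        c(tfi_total = .rtrunc_norm(1, 40, 15, 0, 100), sub)
      } else {
        setNames(rep(NA_real_, 9),
                 c("tfi_total",
                   paste0("tfi_", c("i", "sc", "c", "sl", "a", "r", "q", "e"))))
      }
      z <- matrix(rnorm(spec$t_len * spec$n_rois), spec$t_len, spec$n_rois)
      ts <- z %*% chols[[g]]
      if (spec$smooth_window > 1) {
        ts <- apply(ts, 2, function(col)
          as.numeric(stats::filter(col, rep(1 / spec$smooth_window,
                                            spec$smooth_window),
                                   sides = 2, circular = TRUE)))
      }
      colnames(ts) <- nm
      subjects[[length(subjects) + 1L]] <- c(
        list(subject_id = sprintf("%s%03d", g, k), group = g,
             timeseries = ts, age = age, sex = sex, avg_ht = avg_ht,
             ht_8k = ht_8k, duration = duration, pm = pm, lm = lm),
        as.list(tfi))
    }
  }
  structure(list(subjects = subjects, spec = spec,
                 partition = spec_partition(spec), roi_names = nm),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("fc_cohort: %d subjects (%s); %d ROIs x %d time points\n",
              length(x$subjects),
              paste(sprintf("%s %d", names(table(grp)), table(grp)),
                    collapse = ", "),
              x$spec$n_rois, x$spec$t_len))
  invisible(x)
}

#' Cohort manifest as a data frame
#'
#' One row per subject with group label and all scalar covariates (the
#' time series themselves stay in the subject records).
#'
#' @param cohort an `fc_cohort`.
#' @return Data frame keyed by `subject_id`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "fc_cohort"))
  cols <- setdiff(names(cohort$subjects[[1]]), "timeseries")
  out <- do.call(rbind, lapply(cohort$subjects, function(s)
    as.data.frame(s[cols], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
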
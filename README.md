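# fcnet

Graph-theoretical analysis of resting-state functional brain networks in R.

`fcnet` is for researchers comparing whole-brain functional connectome
topology between clinical groups — the motivating use case is three-group
designs contrasting recent-onset tinnitus (ROT), persistent tinnitus (PT)
and healthy controls (HC) — starting from parcellated ROI time series
(90-region anatomical atlas, one T x N matrix per subject).

The pipeline it implements:

* **Connectivity:** Pearson correlation matrix per subject.
* **Sparsity thresholding:** binary undirected networks with
  |E| = round(S·N(N−1)/2) edges at each threshold of the grid
  S = 0.05–0.18 (step 0.01), so all subjects have identical node and edge
  counts; the small-world regime is verified by the two conditions
  mean degree > 2·log(N) and sigma > 1.1 for all subjects.
* **Topology:** global metrics Cp, Lp, Eglob, Eloc and nodal metrics DC,
  NCp, NLp, Ne, Nle, BC on every thresholded network.
* **Small-world normalization:** gamma = Cp/⟨Cp_rand⟩,
  lambda = Lp/⟨Lp_rand⟩, sigma = gamma/lambda against ensembles of
  degree-preserving (double-edge-swap) random networks.
* **AUC integration:** each metric curve over the sparsity grid collapses
  to its area under the curve, removing single-threshold arbitrariness.
* **Modular connectivity:** intra- and inter-module connection densities
  over the six anatomical modules (frontal, prefrontal, parietal,
  temporal, occipital, subcortical) — 21 measures per subject.
* **Group statistics:** ANCOVA on AUC values with age, sex and hearing
  thresholds as covariates, LSD post hoc contrasts, Bonferroni correction
  for nodal and module families, Shapiro–Wilk gating to
  Kruskal–Wallis/Mann–Whitney or rank-ANCOVA branches, chi-square tests
  for categorical demographics, and Spearman correlations with
  Benjamini–Hochberg FDR.

Because raw clinical data are typically unavailable, the package includes
a first-class synthetic cohort generator (`cohort_spec()`,
`sample_cohort()`) producing Gaussian ROI time series with block-modular
covariance, plantable group-level segregation deficits and covariates with
group offsets, so the entire pipeline is testable end to end against known
ground truth.

## Worked example

```r
library(fcnet)

spec <- cohort_spec(n_per_group = c(ROT = 10, PT = 10, HC = 10), seed = 42)
cohort <- sample_cohort(spec)      # 30 subjects, 90 ROIs x 240 time points
res <- run_pipeline(cohort, nodal = FALSE, modules = FALSE,
                    null_cfg = null_config(n_rand = 20), seed = 42)
summary(res)
```

```
Global AUC metrics by group (mean):
  group    a_cp   a_lp a_eglob  a_eloc a_gamma a_lambda a_sigma
1    HC 0.09101 0.1963 0.01962 0.10220  0.5798  0.08825  0.8959
2    PT 0.09292 0.1912 0.01946 0.10498  0.6324  0.08537  0.9910
3   ROT 0.04547 0.3234 0.06028 0.06712  0.3167  0.14245  0.2870

Group comparison (covariate-adjusted):
  variable statistic         p
1     a_cp    435.73 5.211e-19
2     a_lp    869.37 2.146e-22
3  a_eglob   7434.07 4.690e-33
4   a_eloc    225.10 7.884e-16
...
```

The default generator plants a within-module correlation deficit (factor
0.5) in the ROT group: the summary shows exactly the expected signature —
ROT has roughly half the clustering AUC (`a_cp` 0.045 vs 0.091) and
markedly lower local efficiency (`a_eloc` 0.067 vs 0.102) than HC, i.e.
reduced functional segregation, and the covariate-adjusted ANCOVA flags
the group effect on every integrated metric. Pairwise LSD p-values and
the per-threshold curves live in `res$stats_global` and `res$global`.

Demographic tables use the same machinery, e.g. a chi-square on a
side-of-tinnitus contingency table:

```r
chi_square_test(rbind(PT = c(5, 9, 14), ROT = c(10, 8, 5)))
#> $statistic 5.551814   $df 2   $p.value 0.0623
```

## Package layout

* `R/` — synthetic cohorts, connectome construction, graph metrics
  (Rcpp-backed engine in `src/metrics.cpp`), null models, AUC integration,
  modular analysis, group statistics, pipeline orchestration and
  plain-text IO.
* `inst/extdata/` — six-module partition of the 90-ROI atlas (editable
  TSV) and a node table of tested MNI coordinates.
* `vignettes/fcnet-methods.Rmd` — the methods vignette: model,
  conventions, numerical choices, generator design and limitations.
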
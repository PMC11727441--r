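---
title: "Graph-theoretical analysis of functional brain networks with fcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical analysis of functional brain networks with fcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

## The analysis model

`fcnet` implements the standard graph-theoretical pipeline for resting-state
functional connectomes. The data enter as parcellated BOLD time series — one
T x N matrix per subject, with N = 90 regions of interest (ROIs) of a
whole-brain anatomical atlas and T = 240 retained volumes in the default
design — and leave as group-level statistics on threshold-integrated network
topology.

The stages are:

1. **Connectivity.** The Pearson correlation between every pair of ROI time
   courses gives a symmetric N x N matrix per subject
   (`pearson_matrix()`). The diagonal is never an edge candidate.
2. **Sparsity thresholding.** Rather than a fixed correlation cutoff, a
   *sparsity* threshold S keeps the top K = round(S·N(N−1)/2) pairs by
   correlation magnitude (`binarize_at_sparsity()`), so every subject's
   binary, undirected network has identical node and edge counts and group
   differences reflect relative organization, not overall correlation
   strength. The analysis repeats over the grid S = 0.05–0.18 in steps of
   0.01 (`sparsity_grid()`), the conventional small-world regime for
   90-node networks.
3. **Topology.** On each binary network the package computes the global
   metrics Cp (mean clustering), Lp (characteristic path length), Eglob and
   Eloc (global/local efficiency), and per node: degree (DC), clustering
   (NCp), path length (NLp), efficiency (Ne), local efficiency (Nle) and
   betweenness (BC) (`network_metrics()`).
4. **Small-world normalization.** Cp and Lp are normalized by their means
   over an ensemble of degree-preserving rewired random networks
   (`rewire_preserving_degrees()`, `small_world()`): gamma = Cp/⟨Cp_rand⟩,
   lambda = Lp/⟨Lp_rand⟩, sigma = gamma/lambda. Sigma > 1.1 is the
   conventional small-world criterion, and `determine_regime()` finds the
   contiguous sparsity range on which every subject has mean degree >
   2·log(N) and sigma > 1.1.
5. **AUC integration.** Each metric's curve over the grid is collapsed to
   its area under the curve (`metric_auc()`), removing the dependence on
   any single threshold.
6. **Modular connectivity.** With the six-module anatomical partition
   (frontal, prefrontal, parietal, temporal, occipital, subcortical), the
   package reports the 6 intra-module and 15 inter-module connection
   densities per subject per threshold (`module_connectivity()`).
7. **Group statistics.** AUC values are compared across the three groups
   (recent-onset tinnitus ROT, persistent tinnitus PT, healthy controls
   HC) by ANCOVA with age, sex, average hearing threshold and 8-kHz
   threshold as covariates, LSD post hoc contrasts, Bonferroni correction
   over the nodal (90-node) and module (21-measure) families, and
   Spearman correlations with Benjamini–Hochberg FDR for clinical
   variables (`omnibus_and_pairwise()`, `spearman_fdr()`).

`run_pipeline()` chains stages 1–7 on a cohort object and is deterministic
for a fixed seed; every output CSV records a config hash and the seed.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| sparsity grid | 0.05–0.18, step 0.01 | thresholds over which topology is measured and integrated (dimensionless edge fraction) |
| degree floor | 2·ln(N) | regime condition (1); natural log by default, base configurable |
| sigma floor | 1.1 | regime condition (2), the conventional small-world cutoff |
| `n_rand` | 100 | null networks per ensemble |
| `swaps_per_edge` | 10 | attempted double-edge swaps per edge during rewiring |
| edge ranking | absolute | edges ranked by \|r\|; `"positive"` available |
| AUC rule | trapezoid | left-rectangle rule available for sensitivity analysis |

Two conventions deserve emphasis. First, edges are ranked by **absolute**
correlation by default: sparsity-thresholding practice in this literature
is usually silent on negative
correlations, and absolute ranking is the only choice that keeps the edge
count identity |E| = round(S·N(N−1)/2) exact at every threshold; a
`"positive"` mode is provided for sensitivity analysis. Second, the log in
the degree floor is the **natural** logarithm (2·ln 90 ≈ 9.00): with a
base-10 reading (≈ 3.91) condition (1) would be satisfied everywhere on the
grid and constrain nothing. Note that under the natural-log reading the
floor excludes S ≤ 0.10 for N = 90 (mean degree ≈ 89·S), so the regime
conditions and the conventional 0.05–0.18 grid are not equivalent; the
package applies the rule as stated, makes the base configurable, and ships
0.05–0.18 as the default analysis grid regardless.

## Numerical choices

* **K rounding** uses round-half-away-from-zero, and ties in |r| competing
  for the last edge slot break by lexicographic node-pair order, so
  thresholding is bit-reproducible and edge sets are nested across the
  grid.
* **Disconnected pairs.** Lp and NLp average over *reachable* pairs only
  (the number of excluded ordered pairs is reported per network);
  efficiencies use 1/∞ = 0 and need no exclusion. A penalty-value
  convention was rejected because 90-node functional networks are nearly
  connected in this sparsity regime (largest components typically 88–90 of
  90 nodes) and a
  penalty would leak an arbitrary constant into the AUC.
* **Degree < 2 nodes** take NCp = Nle = 0, the standard convention that
  keeps network means defined.
* **Betweenness** is reported unnormalized (the AUC and statistics layers
  are scale-consistent); a normalization flag exists for cross-N
  comparisons.
* **Null ensembles** use means (not medians) of Cp and Lp, the
  Watts–Strogatz convention; ensemble size 100 and 10 swaps per edge are
  field-standard defaults recorded in the output metadata. Connectedness
  is not enforced on nulls. Complete graphs admit no valid double-edge
  swap and are returned unchanged (so gamma = lambda = sigma = 1 exactly);
  other swap-rigid graphs (stars) additionally raise a warning.
* **ANCOVA** is the sequential linear model `y ~ covariates + group` with
  the F-test on the group factor added last; LSD post hoc contrasts are
  uncorrected pairwise t-tests on the adjusted means using the model's
  residual variance. When the Shapiro–Wilk gate fails and covariates are
  present, the response is rank-transformed and passed through the same
  model (rank ANCOVA) — "nonparametric tests with covariates" has no
  single canonical form, and rank ANCOVA is the least-surprising
  operationalization. Sex enters as a 0/1 indicator; no
  interactions.

## The synthetic cohort generator

Clinical ROI time series are rarely shareable, so `cohort_spec()` /
`sample_cohort()` generate cohorts that emulate its *structure*: three
groups (default 25 subjects each), 90 ROIs x 240 time points per subject,
zero-mean Gaussian time series with a block-modular covariance — unit
diagonal, `r_within` inside each of the six anatomical modules,
`r_between` across modules — and clinical covariates with group offsets
(elevated hearing thresholds in the tinnitus groups, tinnitus duration
< 6 months in ROT and ≥ 6 months in PT). A planted *segregation deficit*
multiplies the within-module correlation of chosen groups
(`effect_map`; default factor 0.5 in ROT), which propagates to lower
clustering and local efficiency exactly as a segregation loss should.

Defaults `r_within = 0.4`, `r_between = 0.1` are calibration choices, not
estimates of any study's empirical connectivity: they sit in the range of
typical resting-state functional correlations and give clearly small-world
thresholded networks. Positive semi-definiteness of every group covariance
is verified at spec construction. Gaussianity is deliberate — the pipeline
consumes only Pearson correlations, which the Gaussian model controls
exactly; there is no hemodynamic model, no scanner artefact, no head
motion, and an optional moving-average smoother (off by default) only
mimics the band-limited character of filtered BOLD. Consequently, passing
tests demonstrate the *pipeline's* correctness and sensitivity under known
ground truth; they say nothing about effect sizes in real tinnitus
cohorts, and the planted factor 0.5 is far larger than plausible clinical
effects.

Subject i draws from RNG substream `seed + i`, so enlarging a cohort never
reshuffles existing subjects, and identical spec + seed reproduces a
cohort bit-identically.

## Problem sizes used in validation

The shipped checks run, per invocation: metric-vs-oracle comparisons on
every isomorphism class of graphs up to 7 nodes plus 250 random graphs of
8–12 nodes; small-world ensembles of 100 nulls on 20 Watts–Strogatz and 20
Erdős–Rényi 90-node graphs; a 2,000-replicate null simulation of the
ANCOVA/LSD layer (n = 75); and 100 replicates of the full
simulate-then-analyse pipeline at 75 subjects x 14 thresholds. These sizes
were chosen to estimate each rate to within a couple of percentage points
while keeping a full validation run in the minutes range on one core.

## Known limitations

* The six-module assignment of the 90 atlas ROIs ships as an editable TSV
  reconstructed from region nomenclature; the graphical source of the
  parcellation is not machine-readable, so module-level results are
  defined relative to the loaded table (whose hash is recorded in output
  metadata).
* Weighted and directed network variants, Fisher z-transforms, lattice
  reference small-world indices (omega, SWP), rich-club/assortativity
  metrics and data-driven community detection are intentionally out of
  scope.
* Group statistics on AUC values assume the homoscedastic linear model;
  the rank-ANCOVA fallback is a pragmatic, not exact, nonparametric
  adjustment.
* On a single Erdős–Rényi draw at N = 90, p = 0.1, sigma fluctuates around
  1 with noticeable variance (few triangles); only ensemble-level
  statements are stable at that size.

## A minimal run

```{r example, eval = FALSE}
spec <- cohort_spec(n_per_group = c(ROT = 10, PT = 10, HC = 10), seed = 42)
cohort <- sample_cohort(spec)
res <- run_pipeline(cohort, null_cfg = null_config(n_rand = 20), seed = 42)
summary(res)
res$stats_global
```
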
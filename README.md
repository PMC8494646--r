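# projcensus

Quantitative machinery for building a cell-type **wiring diagram of a
cortical area** from multi-modal anatomical data. The package implements the
analysis layer that sits between registered, quantified imaging/sequencing
outputs and the biological summary statements: connectivity matrices,
projection clustering, sublayer delineation, barcoded single-neuron
subgrouping, projection-discreteness testing, and bulk-pattern
deconvolution. Every stage can be exercised end-to-end on seeded synthetic
data with planted ground truth.

## Who it is for

Systems neuroscientists and analysts working with:

* **anterograde / retrograde tracer experiments** quantified as labelled
  signal volume per atlas region (e.g. serial two-photon pipelines),
* **barcoded projection mapping** (BARseq-style) count matrices of neurons x
  dissected target areas with spike-in standards,
* **full single-neuron reconstructions** (SWC) registered to an annotation
  volume,
* **soma-depth samples** from retrograde labelling or driver lines.

## What it computes

* `output_fraction_matrix()` / `input_fraction_matrix()` — weighted
  connectivity matrices: per experiment, weight of target *t* is
  `w_t = v_t / sum_j v_j` (fraction of total labelled signal volume,
  injection structure excluded). Retrograde inputs are first cleaned with a
  blank-brain false-positive calibration: per-region threshold
  `mean + k * sd` over brains with no tracer (`k = 6` by default).
* `spearman_complete_cluster()` — agglomerative clustering of matrix rows
  with distance `1 - Spearman rho` and complete linkage, plus
  `layer_enrichment()` (two-sided Fisher exact), `within_cluster_similarity()`
  (mean pairwise rho), and `cluster_contrasts()` (one-way ANOVA + Tukey HSD
  on in-degree; two-way repeated-measures ANOVA for cluster x target).
* `depth_histogram()` / `delineate_layers()` — cortical sublayers as maximal
  contiguous runs of 25-µm soma-depth bins that cluster together (Euclidean,
  complete linkage) by label-source composition.
* `entropy_split()` — recursive binary partitioning of barcoded neurons:
  each split is the presence/absence pattern over at most 3 target areas
  that maximizes the reduction in Shannon entropy (bits) of the laminar
  depth distribution, accepted at a permutation p < 0.05 (the null
  re-maximizes over all candidate patterns per shuffle). `merge_by_laminae()`
  then recombines leaves whose depth distributions are statistically
  indistinguishable (rank-sum, Bonferroni) and whose median depths are
  within 200 µm, never across major classes.
* `xor_discreteness_test()` — are single-cell projection patterns discrete
  types or a continuum? Pairwise XOR distances (regions targeted by exactly
  one of the pair) are compared against fixed-margin shuffles of the binary
  matrix (checkerboard swaps preserving all row/column sums) with a
  one-tailed Levene test on the variance.
* `estimate_composition()` — deconvolution of a bulk regional pattern *b*
  into single-cell cluster proportions: `argmin_x ||A x - b||_2` with
  `x >= 0` (NNLS, Lawson–Hanson) or box constraints (BVLS, default bounds
  0.01–1), where the columns of *A* are cluster-mean fraction vectors
  (clusters with fewer than 15 neurons excluded).
* `synth_config()` + `generate_*()` — seeded generators for all four input
  kinds with planted classes, subgroups, laminar structure, and mixtures.
* `run_pipeline()` — configuration-driven end-to-end run with a
  machine-readable JSON report, also exposed as a CLI
  (`Rscript inst/exec/projcensus run --seed 3 --out DIR`).

## Worked example

Fifteen synthetic tracer experiments (5 each from IT/ET/CT class
archetypes, 20% multiplicative noise, blank-brain background), masked,
normalized, summarized and clustered:

```r
library(projcensus)

cfg  <- synth_config(seed = 1, noise_cv = 0.2)
tr   <- generate_tracer_experiments(cfg)
cal  <- blank_calibration(generate_blank_brains(cfg, tr$ontology), k = 6)
mask <- sweep(tr$signal, 2, cal$threshold, ">")
m    <- output_fraction_matrix(tr$signal, tr$ontology, mask = mask)
m
#> connectivity_matrix (output): 15 x 60

round(division_summary(m, tr$ontology)["average", c("isocortex",
      "striatum", "thalamus", "midbrain")], 3)
#> isocortex  striatum  thalamus  midbrain
#>     0.237     0.128     0.367     0.104

cl <- spearman_complete_cluster(m, k = 3)
cl$assignment
#> IT_01 IT_02 IT_03 IT_04 IT_05 ET_01 ET_02 ET_03 ET_04 ET_05 CT_01 ...
#>     1     1     1     1     1     2     2     2     2     2     3 ...

adjusted_rand_index(cl$assignment, tr$truth)
#> [1] 1
round(within_cluster_similarity(m, cl$assignment), 3)
#> [1] 0.979 0.998 0.987

idist <- injection_distances(tr$injections)
sprintf("%.1f +- %.2f um", idist$mean, idist$sd)
#> [1] "391.1 +- 178.48 um"
```

The division shares are the average fraction of labelled signal per major
brain division; the cluster assignment recovers the three planted tracer
classes exactly (adjusted Rand index 1), and within-cluster mean Spearman
correlations near 1 show the planted archetypes are internally coherent at
this noise level.

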
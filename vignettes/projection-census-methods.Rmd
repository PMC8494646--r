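---
title: "Methods: projection-census analysis of a cortical area"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projection-census analysis of a cortical area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projcensus)
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions behind them, the parameters that matter, and the
choices made where the methodology was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The problem

A cell-type wiring diagram of one cortical area asks, jointly: which brain
regions does the area project to and receive input from, broken down by
projection-neuron class (IT — intratelencephalic, ET — extratelencephalic /
pyramidal tract, CT — corticothalamic)? How are those classes and their
finer subgroups laid out in cortical depth? And are single-neuron
projection patterns discrete types or a continuum? The package implements
the quantitative layer of that program: it starts from *quantified* data
(signal volume per atlas region, barcode counts per dissected area, SWC
reconstructions plus an annotation volume, soma depths) and produces the
matrices, clusters, delineations and tests.

## 2. Region ontology

Regions live in a rooted tree; leaf-level "summary targets" are the
quantification units, and each rolls up to exactly one of 13 major
divisions (isocortex ... spinal cord). Connectivity is tabulated over
*bilateral* targets — each summary target once per hemisphere, ipsilateral
defined as the hemisphere of injection (data files must state it; the
convention is not inferable from signal alone). The packaged default,
`synthetic_ontology()`, is a generated stand-in with the same schema and
314 summary targets (628 bilateral) — the size of the real whole-brain
atlas target list — not real anatomy; users load their own atlas export as
a flat JSON node list with `load_ontology()`, which reports unmatched
parents and duplicate ids rather than guessing.

## 3. Connectivity matrices

**Output (anterograde) weights.** For one experiment, the weight of target
$t$ is $w_t = v_t / \sum_j v_j$: the fraction of total labelled axon
volume, after (a) applying a *true-positive mask* and (b) excluding both
hemispheres of the injected structure (the hemisphere scope of the
exclusion is unstated in the field's descriptions; excluding both is the
conservative choice). Experiments sharing a group label are combined as the
*mean of their normalized rows*, not by renormalizing summed raw volumes —
consistent with "fraction measured from a single experiment or the average"
and robust to brains with different labelling efficiency.

**False-positive calibration.** Segmentation pipelines produce spurious
signal. Brains processed with no tracer ("blank" brains, of which real
pipelines run on the order of 90) estimate a per-region background
distribution; the detection threshold is $\mu + k\sigma$ with sample
($n-1$) standard deviation and $k = 6$ by default. Retrograde input
matrices zero sub-threshold entries *before* normalizing. Raising $k$ can
only zero more entries, so in-degree (count of strictly positive targets
per row) is monotone non-increasing in $k$ — asserted as a property test.

**Masking before clustering.** Spearman rank correlation ranks *all*
columns, so regions carrying pure background noise contribute random ranks
that dilute genuine similarity. The real analyses mask false positives
before clustering; the synthetic pipeline does the equivalent by masking
signal below the blank-calibrated threshold. Without that step,
class-recovery on synthetic data degrades exactly as rank dilution
predicts.

## 4. Clustering of projection patterns

Rows are clustered agglomeratively with distance $1 - \rho_s$ (Spearman,
average ranks for ties) and complete linkage, cut at a user-chosen $k$ —
$k$ is deliberately not automated because the source analyses chose it by
inspecting the dendrogram. Rows with missing entries (e.g. transsynaptic
tracers with masked reciprocal regions) are handled pairwise-complete or
excluded; both are supported because the original analysis excluded such
rows. Correctness is anchored two ways: a brute-force agglomeration oracle
reproduces merge heights and partitions on up to 6 rows, and assignments
are invariant to monotone transforms of the data (a Spearman property).

Cluster-level statistics: two-sided Fisher exact tests for layer enrichment
(checked against direct hypergeometric enumeration), mean within-cluster
pairwise $\rho_s$, one-way ANOVA + Tukey HSD on per-row nonzero-target
counts, and a two-way repeated-measures ANOVA (between: cluster; within:
target area) whose cluster × target interaction tests whether clusters
differ in *where* they project rather than merely how much.

## 5. Sublayer delineation from soma depths

Soma depths are binned every 25 µm from the pia (half-open bins, depth 0 in
the first bin). Each bin is characterized by its *source composition*: raw
counts are first scaled within source (so efficient injections do not
dominate), then normalized across sources within the bin. The bins are
clustered (Euclidean, complete linkage, cut at $k$) and **layers are the
maximal contiguous runs of same-cluster bins**, named in depth order. The
run rule matters: one cluster identity recurring at separated depths yields
several sublayers (how a "superficial/middle/deep" split of one band can
arise), so the number of layers can exceed $k$. The composition feature is
a design choice the source text leaves open (raw counts are supported via
`normalize = FALSE`); composition is the default because bin-occupancy
noise otherwise swamps the source-identity signal — with raw or
per-source-only scaling, planted-boundary recovery fails at realistic
sampling noise, and with composition it is exact within one bin in 20/20
seeded trials (criterion 5).

## 6. Barcoded projection analysis

**Normalization.** Counts are divided by each neuron's spike-in count
(controls per-cell amplification), then, per area, each brain is rescaled
so the mean over neurons with nonzero counts matches across brains
(controls per-brain library depth). The post-condition — equal per-area
nonzero means across brains to 1e-9 — is asserted directly. Areas with no
nonzero neurons in some brain keep factor 1 with a warning.

**Major classes** come from bisecting ("hierarchical") k-means on
`log1p`-transformed strengths: repeatedly split the cluster with the
largest within-ss using k-means++ with 10 restarts. The divisive reading of
"hierarchical k-means" is one of two possible interpretations; it is used
because it yields a deterministic number of leaves and nests naturally.
Labels (CT / L5 ET / IT Str+ / IT Str−) are annotated post hoc from
centroid means over user-named thalamic, striatal and medulla/pons areas.

**Entropy-reduction subgrouping.** At each node, all presence/absence
patterns over subsets of ≤ 3 areas are enumerated (the cap follows the
source method). For candidate membership $m$, the score is
$\Delta H = H(D) - \frac{n_1}{n} H(D_1) - \frac{n_0}{n} H(D_0)$, Shannon
entropy in bits of the 25-µm-binned depth distribution. The best candidate
is accepted if its permutation p-value is below 0.05 (uncorrected across
nodes, as stated by the source). The null construction was unspecified;
this implementation **re-maximizes $\Delta H$ over all candidates in every
permutation** (max-T). Fixing the selected pattern instead would ignore
selection over thousands of candidates and inflate the type-I rate far
above $\alpha$; with max-T the measured null acceptance rate is ≤ 5% (± 2
SE over 400 runs, criterion 3b). Recursion stops below 20 neurons (not
specified by the source; small nodes make both the entropy estimate and
the permutation null unstable).

**Laminar merging.** Leaves are recombined bottom-up (closest mean
projection vectors first): a pair merges iff the rank-sum test on depths is
non-significant after Bonferroni correction — denominator = candidate pairs
examined in the current pass by default, a global option is provided, since
the family was unspecified — AND median depths differ by ≤ 200 µm AND both
share a major class (merging stops at class level).

**Conditional probabilities** $P(x\mid y{=}1)$, $P(x\mid y{=}0)$ are
empirical frequencies on an explicit stratum; the exact decomposition
$P(x|y{=}1)P(y{=}1) + P(x|y{=}0)P(y{=}0) = P(x)$ holds on any finite
stratum and is asserted. Binarization (here and for splitting) is raw
count ≥ 1, configurable; the source rule was unstated.

## 7. Single-neuron quantification and tests

**SWC.** A reconstruction must be a single tree: one root, no cycles, at
most two children per non-root node. Violations are named (breaks, cycle,
trifurcation). Cable length is the sum of parent–child Euclidean segments.

**Region assignment.** Each axon segment is subdivided into ≤ 1 µm
sub-segments; each sub-segment's length goes to the region of its midpoint
voxel in the annotation volume (the deterministic refinement of per-voxel
quantification). Out-of-volume length lands in an explicit "unannotated"
bucket. Fractions are computed after summing hemispheres, rows normalized
to 1.

**Discreteness (XOR + shuffle + Levene).** The XOR distance between two
neurons is the number of regions targeted by exactly one. The null of
"continuous targeting consistent with the regional pattern" is realized as
fixed-margin randomization: iterated 2×2 checkerboard swaps (burn-in 10×
the number of ones) preserving every row and column sum exactly — asserted
per shuffle. An independent-Bernoulli null is provided as an option. The
one-tailed Levene test (classic mean-centred form; with two groups the
statistic is the squared t on absolute deviations, so the one-tailed p
comes from the t directly) asks whether the observed distance variance
exceeds the shuffled one. Pairwise distances are not independent, which the
test ignores — as does the field's usage; measured size on unstructured
Bernoulli data stays within the acceptance bound (criterion 4).

**Deconvolution.** $A x \approx b$ with columns of $A$ the cluster-mean
fraction vectors (clusters under 15 neurons excluded), solved by NNLS
(Lawson–Hanson active set, implemented in-package because the original R
solver packages are not available in the runtime) or BVLS with bounds
(0.01, 1), solved as a box-constrained QP via L-BFGS-B — a deliberately
different algorithmic route so the two methods cross-check each other;
tests require agreement within 0.02 on well-conditioned problems, with a
grid-search oracle as a third route. Reported proportions are renormalized
to sum 1 and the residual is reported relative to $\lVert b\rVert^2$.

## 8. The synthetic world

The generators state a world once; they are not tuned to tests.

* **Tracer experiments**: 3 classes × 5 experiments; per-target signal =
  archetype weight × total volume (1e5) × mean-1 lognormal noise with
  cv = 0.2 × plus zero-truncated Gaussian background (mean 2, sd 1) — the
  background/total ratio makes sub-threshold regions plausible but
  non-trivial. Class archetypes concentrate weight on class-typical
  divisions (IT → cortex+striatum bilateral; ET → subcortical,
  ipsi-dominant; CT → thalamus) with a seeded sparse Dirichlet split within
  divisions. Lognormal multiplicative noise and Poisson counts are the
  package's own choices (nonnegative, overdispersion-controllable,
  standard for volumes and counts); the source specifies none.
* **Injection coordinates** jitter around class centres with per-axis sd
  195 µm: for 3D Gaussian jitter the mean pairwise distance is
  $\sigma\sqrt{2}\,\mathbb{E}[\chi_3] \approx 2.26\sigma \approx 440$ µm,
  matching a compact injection grid within one cortical area.
* **Blank brains**: 90 by default, within the 89–97 range real pipelines
  report.
* **Barcoded neurons**: 1000 neurons, 8 areas, 2 brains (the two-brain
  normalization case) with library scale factors (1, 1.5); spike-in mean
  100; subgroup patterns use digit strings where class-defining projections
  are strong (mean count 50) and subgroup-distinguishing ones weak (×0.1) —
  mirroring graded projection strengths, and necessary for the stated world
  to be self-consistent: if within-class subgroups differed in strong
  projections, no 4-way clustering could recover classes. Depths are
  truncated normals in [0, 1200] µm (spans L1–L6b at 25-µm bin scale).
* **Single cells**: 3 cluster archetypes over 6 regions, per-cell fractions
  Dirichlet with concentration 100 (Inf = noiseless). Optional
  materialization writes each cell as a monotone-in-x SWC polyline through
  a slab annotation volume; because the path is monotone, each interior
  slab contributes exactly its width of horizontal length, which the
  generator budgets explicitly so re-quantified fractions match the table
  within 5% (round-trip oracle).

What a green test does **not** establish: generators draw independent
per-region noise (no spatial correlation along axons), contain no
registration error, no partial injections, no barcode collisions or
basecalling errors, and archetypes are cleanly separated. Green means the
machinery is correct and well-calibrated on a faithful stated world, not
that real data will be as kind.

## 9. Numerical choices and degenerate inputs

* Row normalization guarantees sums of 1 ± 1e-9; all-zero rows stay zero
  with a warning (never NaN).
* Constant rows make Spearman undefined → error naming the row.
* Singleton clusters have undefined within-cluster similarity → `NA`.
* Permutation p-values use the add-one estimator $(b+1)/(n+1)$, so p = 0 is
  impossible and the test is exact-valid.
* Zero spike-in neurons are dropped with a warning; a brain with no nonzero
  counts in an area keeps scale factor 1 with a warning.
* Ties in ranks use the average-rank convention throughout.
* Seeds: every stochastic routine takes an explicit seed and restores the
  global RNG state on exit; derived seeds stay below $2^{31}$.

## 10. Known limitations

* The entropy-split candidate enumeration is $O\!\left(\sum_{s\le 3}
  \binom{A}{s} 2^s\right)$ per node per permutation; fine for tens of
  areas, slow for hundreds.
* Checkerboard-swap mixing is diagnosed only by the burn-in heuristic
  (10× fill), not by a formal mixing bound.
* The repeated-measures ANOVA uses the classical sphericity-assuming F;
  no Greenhouse–Geisser correction.
* `merge_by_laminae` merges greedily (closest pair first); it does not
  search over merge orders.
* The pipeline caches stage outputs in memory within one run; it does not
  resume across processes.
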
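---
title: "Methods: multilayer morphometric similarity networks and flexibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilayer morphometric similarity networks and flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design choices behind
`msnflex`, in the order the pipeline applies them.

## From morphometry tables to one subject's network

The input unit is a regions × 9 table of FreeSurfer-style surface features
per subject (number of vertices; surface area, mm²; gray volume, mm³;
average thickness and its s.d., mm; mean curvature, mm⁻¹; Gaussian
curvature, mm⁻²; folding and curvature indices, unitless), on either the
Desikan-Killiany (68 regions) or Destrieux (148 regions) parcellation. Four
feature subsets are first-class citizens: `9f` (all nine), `5f` (volume,
area, thickness, Gaussian curvature, folding index), `4v` (the volumetric
four) and `4c` (the curvature four). With both atlases, each subject yields
8 networks.

Construction steps, and the conventions each one fixes:

1. **Group-median outlier replacement.** For each (region, feature) cell
   across subjects, values further than 3 scaled MADs (1.4826 × MAD,
   consistent with a Gaussian s.d.) from the group median are replaced by
   that median. A cell column with zero MAD is never touched. The threshold
   is a parameter (`n_mad`); 3 is the conventional default of median/MAD
   outlier filters. At least 3 subjects are required.
2. **Within-subject z-normalization.** Each selected feature is standardized
   across regions *within the subject*, because the subsequent correlation
   compares regional feature vectors, which must be commensurate within a
   subject. The alternative — standardizing each feature across subjects —
   would leak group information into individual networks; the within-subject
   convention is the package's choice. The sample (n − 1) s.d. is used,
   matching `scale()`, so `c(1, 2, 3)` maps to `c(-1, 0, 1)`.
3. **Correlation and Fisher transform.** Edge weight = `atanh(r)` of the
   Pearson correlation between two regions' k-vectors (k = 4, 5 or 9).
   Correlations with `|r| ≥ 1 − 1e-7` are clipped to `1 − 1e-7` first:
   `atanh` is monotone, so clipping keeps all weights finite without
   reordering edges. A region whose profile has zero variance gets zero
   rows/columns and a warning rather than NAs.
4. **Fixed-density thresholding.** The retained edge set is the union of 4
   successive *edge-disjoint* maximum spanning trees on absolute weight,
   each tree built on the graph minus previously retained edges; retained
   edges keep their signed weights. On a complete matrix with distinct
   absolute weights this keeps exactly `4 (N − 1)` edges — 588 at N = 148,
   i.e. 5.405…% density, printed as 5.4% — and the same count for every
   subject, which is what makes networks comparable across a cohort. The
   spanning-tree construction also guarantees connectivity, unlike plain
   top-k thresholding. Ties in absolute weight are broken lexicographically
   by (i, j) so results are deterministic; the tree count `n_trees` is a
   parameter. The Kruskal/union-find construction is in-package because the
   tie-break rule is part of the contract; tests cross-check the first tree
   against `igraph::mst`. If a residual graph disconnects, the maximum
   spanning forest of that step is kept and the shortfall is reported.

## Multilayer modularity

Subjects' MSNs become slices `s = 1..L` of a multilayer network with
*ordinal* coupling: node `i` in slice `s` is linked, with strength ω, to
itself in slices `s ± 1` only. The quality of a joint partition `g` is

`Q_ml = (1/2μ) Σ_ijsr { (A_ijs − γ_s P_ijs) δ_sr + δ_ij C_jsr } δ(g_is, g_js)`

with `2μ = Σ_jr κ_jr`, where `κ_jr` sums node `j`'s intra-slice absolute
strength and its coupling strength in slice `r`.

**Signed weights.** The configuration null `k_i k_j / 2m` is ill-defined on
signed graphs, so each slice's modularity matrix uses the two-part
decomposition `A − γ (P⁺ − P⁻)`, where `P±` are computed on the positive and
negative weight parts separately (each part's null preserves its total
weight). This follows the common signed extension of modularity and the
principle that positive and negative association structure should not be
averaged into one null. The exported `single_layer_Q()` reports the
per-sign-normalized index `Q⁺/2m⁺ − Q⁻/2m⁻`; for nonnegative networks both
conventions coincide with classical normalized modularity (two equal
disjoint cliques under the correct split give exactly 0.5). An
absolute-weight mode is deliberately not offered at the stack level: taking
`|A|` would reward placing strongly *dissimilar* regions together.

**Parameters.** Default `γ_s = 1.0` for all slices (larger values favor more,
smaller communities; 1.1 is a conventional preset for lobe-scale divisions of
the 68-region atlas and can be passed per slice). A per-slice re-weighting
scheme for γ is not specified beyond this, so uniform γ is the default.
ω defaults to 1.0 and is always recorded on the stack and in run manifests,
because flexibility depends on it strongly (see the limits below). Both are
unitless, on the scale of the Fisher-z edge weights.

**Optimizer.** A generalized Louvain heuristic on the supra-modularity
matrix: phase 1 sweeps (node, layer) units in a seeded random order, moving
each to the community with maximal positive gain (ties break toward the
incumbent, then the lowest label; on signed matrices a unit whose every
attachment is negative may open a fresh singleton community); phase 2
aggregates communities into super-nodes; the phases repeat until stable.
The quality trace across passes is non-decreasing and each run is
deterministic given its seed. `sample_best_partition()` draws `n_samples`
(default 1000) restarts and keeps the maximum-quality partition — the first
restart from the classical all-singletons start, later restarts from seeded
random initial partitions. Random initialization matters: singleton starts
funnel into the layer-aligned local optimum created by the coupling, and on
small signed stacks every singleton-start restart can land there; random
restarts restore the guarantee, verified exhaustively in the test suite.
Labels are canonicalized by first appearance in (layer, node) order, and the
reported `Q_ml` always equals a direct re-evaluation of the quality sum from
the stack and label matrix (`evaluate_Qml()`, asserted to 1e-10).

**Move tolerance.** Gains must exceed `1e-12` to trigger a move, so floating
ties cannot cycle.

## Flexibility and hubs

`f_i` counts label changes over the `L − 1` consecutive slice pairs; `F` is
the node average. Labels are compared raw within the one supra-partition —
valid because the optimizer labels all layers jointly — so no post-hoc
module matching is applied. Consequences worth knowing:

- At ω = 0 layers are labeled independently and community identities are
  not aligned across slices, so flexibility is near its maximum regardless
  of structure; at ω → ∞ labels freeze and flexibility is 0. Flexibility is
  therefore only interpretable *at a recorded ω*.
- Aggregations: lobe level (6 divisions: cingulate, frontal, insular,
  occipital, parietal, temporal) and cognitive networks (DMN, SN, VIS, CEN;
  regions mapped to `"none"` are excluded). Group-size-weighted group means
  reconstitute `F` exactly. The region → cognitive-network lookup shipped
  under `inst/extdata/` is the package's own documented configuration and is
  meant to be replaced when a project has its own assignment.
- Hubs: per feature set, the top and bottom `⌊pct · N⌋` regions by `f`
  (7 per tail at 5% of 148; the floor rule is the package's explicit
  rounding choice), merged across feature sets into de-duplicated union
  lists with provenance. A region may appear in both merged lists (flexible
  under one feature set, inflexible under another); both memberships are
  kept and flagged rather than silently dropped.

## Bootstraps, groups and tests

`bootstrap_ensemble()` resamples subjects with replacement at cohort size
(default 500 bootstraps), orders each resample randomly or by ascending
age/IQ (ties by subject id; sorting cancels unequal covariate step sizes
between layers), and re-optimizes each stack. Everything derives from one
master seed.

Group schemes: IQ groups split at mean ± 1 s.d. — boundary subjects go to
the middle group ("away from the mean" read strictly) — with optional seeded
subsampling of the middle group to the larger tail's size for balanced
tests. Age uses 12 bins: ten 5-year bins from age 6, an 11th bin [56, 65)
and a 12th [65, 85]. The conventional printed anchors for these bins
(6–11, ..., 60–65, 65–85) cannot all be 5 years wide and still tile the
range, so the package fixes the breaks above and documents them; ages 7, 63
and 70 land in bins 1, 11 and 12 respectively.

Statistics are deliberately standard: studentized one-sample
Kolmogorov–Smirnov against the normal (note the studentization makes the
test conservative; at n = 500 a uniform sample is *not* reliably rejected
at the 1% level — the suite's power check uses n = 2000), Kruskal–Wallis on
the χ² scale with tie correction (the `{1,2,3},{4,5,6},{7,8,9}` example
gives H = 7.2 exactly) gated Holm-adjusted pairwise rank-sum follow-ups,
and Pearson correlations of per-subject mean positive/negative retained
weights with age or IQ. An empty sign class yields a flagged `NA`, never a
zero.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical shape the analysis assumes: 198
subjects by default, ages uniform on [6, 83], IQ ~ Normal(100, 15) truncated
to [55, 145], sex recorded but unused downstream. Features are generated on
realistic raw scales (thickness ≈ 2.5 mm, volumes in the 10³–10⁴ mm³ range)
so the z-normalization stage does real work. Regions in the same block of
`block_structure` (default: the atlas lobes, giving the planted lobe-aligned
structure) share a 9-dimensional block signature; a subject's region profile
is `√effect · signature + √(1 − effect) · noise`. Signatures are
orthonormalized columns of a Gaussian matrix (hence ≤ 9 blocks), so `effect`
is interpretable as the within-block correlation against a near-zero
cross-block baseline, and the implied covariance is positive semidefinite by
construction. `effect = 0` gives uncorrelated regions; defaults
(`effect = 0.6`, `noise_sd = 1.0`) give recoverable but noisy structure with
between-subject variability. `generate_drifting_cohort()` extends this to
planted dynamics: a fixed set of `q` switcher regions cycles through the
blocks between every consecutive layer, so perfect recovery implies
`F = q/N` (switchers at f = 1, everyone else 0).

What the generator does *not* emulate: ageing trajectories of morphometry,
sex differences, spatial autocorrelation on the cortical sheet, scanner/site
effects, or heavy-tailed feature noise. Passing recovery tests therefore
demonstrates algorithmic correctness on data satisfying the model's own
assumptions, not robustness to real-data pathologies.

## Problem sizes in the test suite

Tests verify the optimizer against exhaustive search over all set partitions
on 128 seeded random signed stacks with `N · L ≤ 10` (up to 115 975
candidate partitions per instance; the count grows as the Bell numbers, so
exhaustive certification beyond ~12 units is not proportionate). Planted
recovery runs a 30-subject, 68-region cohort at `effect = 0.8`,
`noise_sd = 0.2`, and drifting stacks of 24–30 regions × 8–10 layers;
calibration suites use 500 null simulations. These sizes are the package's
validation choices; all thresholds (> 90% block agreement, |F − q/N| < 0.05,
type-I error in [0.03, 0.07]) are stated in the tests themselves.

## Known limitations

- Louvain-style optimization is a heuristic: on large stacks the sampled
  maximum is near-optimal, not certified (certification exists only at toy
  sizes, above).
- Flexibility inherits label-identity semantics from the joint optimization;
  comparing flexibility across runs with different ω (or between ω = 0
  ensembles and coupled ensembles) is not meaningful.
- The cognitive-network lookup is configuration, not ground truth.
- Dense supra-matrices scale as `(N L)²` memory; a 148-region, 198-layer
  stack (~29 000 units) is near the practical ceiling of this
  implementation.
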
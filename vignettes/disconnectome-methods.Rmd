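---
title: "Methods: longitudinal structural disconnectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal structural disconnectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Focal brain lesions damage white matter far beyond their own boundary: a
lesion anywhere along a fiber pathway disconnects the regions that pathway
links. This package quantifies that effect against a reference (healthy)
streamline connectome and tracks it over time, following the atlas-based
lesion-quantification approach used in stroke disconnectome studies.

The ingredients are:

* a **parcellation atlas**: an integer-labeled voxel volume whose parcels
  are the connectome nodes, each assigned to one resting-state network
  (RSN);
* a **reference streamline set**: 3D polylines, each ending in two distinct
  parcels, giving a healthy streamline count `healthy(i,j)` per parcel
  pair;
* **binary lesion masks** at two or more timepoints on the same grid.

For each timepoint `t` and parcel pair `(i,j)`, the *disconnection
fraction* is the proportion of that pair's reference streamlines
intercepted by the lesion; the *spared fraction* is its complement. The
patient-weighted connectivity is

```
weighted(i,j,t) = healthy(i,j) * spared(i,j,t)
```

an estimated surviving streamline count bounded above by the healthy
count. Binary connectivity thresholds the weighted matrix at zero:
strictly positive weights are existing connections; zeros arise either
because every reference streamline of the pair is intersected or because
the healthy atlas has no streamlines there.

A streamline counts as intercepted if **any** point of its polyline,
densified to at most one-voxel spacing, falls in a lesion voxel — no
minimum overlap length. This is the most sensitive reading of
"intercepted", and it makes the measure monotone in the lesion: a strictly
larger mask can never disconnect less.

## Longitudinal classification

For each transition (every consecutive session pair plus first-to-last;
with sessions S1, S2, S3 that is S1→S2, S2→S3, S1→S3), every unordered
edge receives exactly one of five categories from the zero/non-zero status
of its weights:

* **disconnection** — present at the earlier timepoint, absent at the
  later one;
* **re-emerging** — absent, then present (typically uncovered by lesion
  shrinkage);
* **over-connection** — present at both, relative increase strictly above
  the threshold (default 10%);
* **persistent-other** — present at both, not over-connected;
* **absent-both**.

Relative change is `((w_followup − w_baseline)/w_baseline) × 100`.
Normalized counts divide each category's count by the number of existing
connections at the earlier timepoint.

The edge-level analysis refines persistent edges into substantial
increases / decreases / stable against the same ±threshold, after
screening baselines against a floor: the 5th percentile of all non-zero
baseline edge weights of the transition (linear interpolation between
order statistics). Relative change is meaningless at near-zero baselines,
and the floor removes exactly those edges. Per network, classed edges are
attributed to **both** endpoint networks — once per network, so an
intra-network edge contributes once — and the net change is increases
minus decreases. A sensitivity sweep repeats the analysis at 5%, 10% and
20% and reports whether each network's net-change sign is preserved.

Network **vulnerability** aggregates the per-edge loss
`healthy − weighted` per RSN: within-network loss sums intra-network
pairs, between-network loss sums pairs with exactly one endpoint in the
network (each cross-network edge is therefore counted in two networks'
between sums, and global totals use a ½ correction). Each raw loss is
normalized by the same network's healthy total of the same kind. We chose
per-network denominators rather than the global healthy total: only under
per-network normalization can a small, focally damaged network show
vulnerability of tens of percent, which is the behaviour the measure is
meant to expose; with a global denominator every small network would be
pinned near zero.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `over_threshold_pct` | 10 | strict relative-increase threshold (%) for over-connections and substantial changes |
| `sensitivity_thresholds` | 5, 10, 20 | sweep values (%) for the robustness check |
| floor percentile | 5th, linear interpolation (type 7) | baseline screen for percentage-change analysis |
| densification step | 0.5 voxel | maximum point spacing for interception tests |
| `n_bins` (NMI) | 32 | joint-histogram bins for registration QC |

Threshold comparisons are *strict*: a change of exactly 10% at the 10%
threshold is not an over-connection and not substantial. A baseline weight
exactly equal to the floor is retained ("below the floor" excludes).

## The synthetic cohort

No patient imaging ships with the package; a generator produces cohorts
with exact ground truth so every stage is testable end to end:

* **atlas** — Voronoi cells of seed voxels drawn on the grid. This
  guarantees non-empty, compact parcels with one line of logic; every
  network is used at least once.
* **streamlines** — random parcel-pair endpoints at voxel centers joined
  by an arc bent at a jittered midpoint, densified to sub-voxel spacing.
  The healthy connectome counts streamlines per pair, so its minimum
  non-zero entry is 1 — matching the convention that an existing
  connection means at least one spared reference streamline.
* **lesions** — spheres with per-timepoint center, radius and optional
  uniform center jitter. Shrinking radii with a fixed center give exactly
  nested masks; jitter emulates boundary shift; a radius that grows again
  emulates transient regrowth (negative percent volume change). Ground
  truth disconnection fractions come from a deliberately plain
  per-streamline, per-point brute-force loop, independent of the
  vectorized engine.

One master seed drives everything; each stage derives its own child seed,
so adding a stage never changes earlier stages, and the same
configuration always regenerates bit-identical data.

What the generator does **not** emulate: realistic brain geometry or
lesion morphology, diffusion signal, tractography errors, or registration
error. The sphere-with-jitter lesion model is a stand-in chosen for its
analytic volume and controllable nesting, not a claim about real lesion
evolution. Passing tests therefore demonstrate the correctness of the
computations, not the biological fidelity of the inputs.

## Numerical choices

* **Interception sampling.** "Intercepted" is defined at the level of
  densified sample points: each polyline segment `A→B` is
  sampled at `A + (k/n)(B − A)`, `n = ceil(|B − A|/0.5)`, and a
  coordinate `x` maps to voxel `floor(x) + 1` (1-based), clamped to the
  grid. Engine and oracle share this sampling contract (and hence agree
  exactly in floating point) but implement it independently — vectorized
  index lookup versus a scalar loop with early exit.
* **Threshold comparisons** are made on the raw ratio
  `(w_b − w_a)/w_a` against `threshold/100`, not on the ×100 percentage,
  so a weight pair like (10, 11) sits exactly at a 10% threshold without
  floating-point spill.
* **Percentile.** The floor uses R's default quantile type 7 (linear
  interpolation); e.g. weights 1..100 give 5.95. The variant is recorded
  in the run manifest.
* **Degenerate inputs.** Two empty masks have DSC 1 (perfect agreement of
  nothing); percent change from a zero baseline volume is an error, and
  to a zero later volume is 100; a constant image has undefined NMI
  (error); an all-zero baseline matrix has no floor (error); networks
  with no healthy connectivity of a kind report 0% vulnerability with an
  explicit flag.
* **Percent display.** Report columns round to one decimal and drop a
  trailing ".0" (54.01 prints as "54"); stored values are never rounded.

## Problem sizes

The test suite and the acceptance script run cohorts of 14³–24³ voxel
grids with 8–30 parcels and 80–500 streamlines (20 random cohorts for the
engine-versus-oracle equivalence, 10 nested-lesion cohorts for the
monotonicity properties), plus one 48³ / 1035-parcel / 21-network atlas
generation to exercise full-scale parcel counts. These sizes give exact,
exhaustively checkable ground truth; the computations themselves are
resolution-independent.

## Limitations

* Connectivity weights are proportional sparing of reference-atlas
  pathways, not direct measurements of axonal strength; "increased
  connectivity" means more spared reference streamlines, nothing more.
* The pipeline performs no registration; all inputs must already share
  one grid. NMI is provided as a QC metric only.
* Counts are descriptive. With single subjects followed longitudinally
  there is no replication, and the package deliberately computes no
  hypothesis tests; the clinical side-by-side table is explicitly
  non-inferential.
* Tract-level (named-bundle) summaries and graph-theoretic metrics are
  out of scope.
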
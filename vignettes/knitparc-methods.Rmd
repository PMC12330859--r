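---
title: "Connectivity-profile parcellation with knitparc: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-profile parcellation with knitparc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

The thalamus relays and integrates signals between essentially all cortical
and several subcortical territories, and its internal nuclei differ mainly in
*where* they connect, not in how they look on structural MRI. `knitparc`
parcellates such a seed structure from resting-state BOLD fMRI by clustering
each seed voxel's *functional connectivity profile*: the vector of Pearson
correlations between the voxel's time series and R target regions (R = 40 in
the bundled default configuration). Two voxels belong to the same functional
unit when their profiles point in the same direction, regardless of overall
connectivity strength — hence clustering uses **spherical k-means** (cosine
distance: unit-normalized profiles, centroids renormalized after each
averaging step).

The conventional baseline is also provided: **winner-takes-all (WTA)**
assignment, where each voxel is given the single lobe (temporal, parietal,
frontal, occipital, limbic) with the largest partial correlation, controlling
for the other four lobes. WTA caps the number of units at the number of
target parcels and discards all information except the argmax; the package
exists to quantify what that discards.

## The FC definition

Voxel-to-ROI FC is the **mean of correlations**: Pearson r between the seed
voxel and *every voxel of the ROI*, then averaged across the ROI. This is not
the same number as the correlation with the ROI's mean series, and the
difference matters (correlation with a mean series is biased upward for large
homogeneous ROIs). Both orders exist in the package, each where it belongs:
`voxelRoiFC()` implements mean-of-correlations for profiles;
`roiMeanSeries()` feeds correlation-of-averaged-series only to the ROI-ROI
matrices (`roiRoiConnectivity()`), which are defined on averaged series.

Correlations are variance-stabilized with the Fisher-Z transform
(z = atanh r, with |r| clipped at 1 - 1e-7 so degenerate synthetic inputs
stay finite; clipping is reported) before any averaging across subjects.

## Preprocessing

The fixed order is discard → smooth → low-pass → z-score
(`preprocessBold()`):

* **discard**: the first 5 timepoints are dropped (steady-state approach).
* **smooth**: 3 mm FWHM isotropic Gaussian, separable convolution with
  mirror-reflected boundaries; sigma per axis is FWHM/sqrt(8 ln 2) converted
  to voxel units from the affine.
* **low-pass**: 0.08 Hz cutoff. The source text does not state a filter
  family or order; the package uses a 4th-order Butterworth applied
  forward-backward (zero phase), the standard choice in resting-state
  pipelines, with steady-state initial conditions and odd-reflection padding
  so constants pass exactly. This is recorded as a configurable default, not
  a claim of fidelity to the original implementation.
* **z-score**: per-voxel mean 0, population SD 1 (denominator n; Pearson
  correlation is invariant to this choice, so it is cosmetic but fixed).
  Constant series inside the analysis mask are a hard error; outside, they
  are zeroed silently.

## Bootstrapping, consensus and uncertainty

Two resampling schemes quantify stability:

* **subjects bootstraps** (default 40): each replicate draws
  ceiling(75% · N) subjects without replacement, averages their Fisher-Z
  profiles, clusters, and is label-matched to a reference (the first
  replicate, or an external parcellation for cross-group comparisons) by the
  Hungarian algorithm with cost = −(voxel overlap); −IoU is available as an
  option.
* **timepoints bootstraps** (default 10, 25 subjects): a fixed random
  subject subset; each replicate keeps floor(75% · t) timepoints, drawn
  without replacement and kept in temporal order (preserving the low-pass
  structure), before FC is recomputed. This scheme removes the subject-count
  confound when comparing age groups of different sizes.

The **consensus** is the per-voxel majority label (ties to the smallest
label id — deterministic and order-independent), followed by small-component
pruning: 26-connected components smaller than 16 voxels whose face-adjacent
(6-connected) outside neighbors are more than 50% one non-background label
are absorbed into that label, repeated to a fixed point so the operation is
idempotent. Pruning runs after the majority vote; a per-replicate variant is
available (`pruneSmallComponents()` on members) for sensitivity analyses.

The **uncertainty map** is U(v) = 1 − N<sub>c*</sub>(v)/N<sub>total</sub>,
the complement of the majority-label proportion: 0 where all replicates
agree, at most 1 − 1/N<sub>total</sub>. (The source description reads
"inverse of the proportion"; the complement, not the reciprocal, is the
reading consistent with a bounded quantity that is 0 under certainty, and is
what the package implements.) The scalar summary uBar sums U(v) over all
seed voxels — each voxel belongs to exactly one consensus cluster, so the
per-cluster double sum does not double-count — and divides by the group's
subject count so groups of different sizes are comparable.

**Choosing k**: `selectK()` tabulates, per candidate k (default 2..7), the
mean CoV of IoU (sd/mean of intersection-over-union across all replicate
pairs, per cluster, averaged over clusters) under both schemes, plus the
mean ± sd cosine silhouette. It deliberately declares no winner: the number
of clusters is a study-level judgement, and the table reproduces the
evidence that judgement needs. Degenerate CoV values (single pair, zero mean
IoU) are flagged rather than silently reported as 0 or infinity; clusters
empty in every member are excluded and listed.

## Summary metrics

* `clusterProfiles()`: per ROI, the median FC within each cluster in each
  subjects-bootstrap, averaged across bootstraps; then z-scored across the
  ROI axis, with |z| > 1 flagged significantly (dis)connected. Bilateral
  merging of L/R ROI columns is an option for reporting.
* `relativeVolumes()`: cluster voxels / seed voxels per replicate (rows sum
  to 1), mean ± sd across replicates.
* `symmetryIndex()`: labels mirrored across the mid-sagittal grid plane in
  both directions; index = mean of the two per-hemisphere agreement rates,
  1 = perfectly symmetric. Mirrored voxels landing outside the opposite
  mask count as disagreement. The mirror is a pure grid reflection: inputs
  must be midline-aligned (template space); the synthetic phantoms are
  constructed that way.
* `lateralityIndices()`: Ri = mean FC(right seed → right ROIs) / mean
  FC(left seed → left ROIs), Rc the crossed analogue. Signed FC is used by
  default (the ratio form targets values near 1); an absolute-value variant
  is a flag. Midline ROIs are excluded.
* `globalThalamicConnectivity()`: mean |FC| per ROI over all voxels and
  subjects pooled (no bootstrapping), bilaterally averaged per pair, midline
  ROIs unmerged.
* `roiRoiConnectivity()`: per age group, the subject-averaged correlation
  matrix of ROI mean series over the group's first n subjects in metadata
  order (a deterministic choice; the source does not state a selection
  rule), plus consecutive-group difference matrices and the mean absolute
  off-diagonal as a global scalar.

# The synthetic phantom

`makePhantomAnatomy()` + `simulateCohort()` generate the entire test bench:
ROI parcels as boxes along the lateral faces (one-voxel gaps limit smoothing
cross-talk between stacked parcels), two mirror-placed seed blobs split into
k contiguous slabs, and per-subject BOLD where each ROI voxel carries an
independent unit-variance white Gaussian source (optionally shared within
bilateral pairs — homotopic connectivity) plus N(0, noiseSd) voxel noise,
and each seed voxel carries the weighted source mixture of its planted
cluster. Near cluster borders the weights are linearly blended (weight of
the nearest other cluster ramps from 0.5 at the interface to 0 over
`borderMixWidth` voxels), which is what makes the bootstrap uncertainty
concentrate at borders, as it does in real data.

What the phantom deliberately does **not** emulate: hemodynamic
autocorrelation, motion, field inhomogeneity, age-dependent signal models.
Passing tests therefore demonstrate that the *estimators and algorithms* are
correct and stable under known ground truth — not that real neonatal data
meet the model's assumptions.

Default conditions (chosen once as the reference test-bench): 24³ grid of
2 mm voxels, 10 ROIs (5 bilateral pairs, one per lobe), k_true = 5, 600
timepoints at TR = 0.392 s, noiseSd = 1 (unit source-to-noise), 1-voxel
border blend, 10 subjects. The "pulvinar analogue" variant plants one
cluster whose profile loads two ROI pairs belonging to lobes that other
clusters already dominate (14 ROIs, mixed pairs 6 + 7): profile clustering
gives it a dedicated cluster; WTA, by construction, cannot.

The trend analyses use deliberately harder variants, sized to run on one
CPU in minutes: for the variability-vs-k trend a 3-cluster phantom with
dominant weight 0.4 and no border blending (the only real structure is the
planted k, so extra clusters must split on noise); for the
variability-vs-timepoints trend a low-contrast phantom (dominant weight
0.12, no border blend, 2 subjects) where FC sampling noise is the limiting
factor, so quadrupling the series length visibly tightens the bootstrap
ensemble. Border blending is excluded from both trend phantoms on purpose:
a blend band is itself a coherent profile direction, i.e. extra structure
that competes with the planted partition and would confound a trend whose
mechanism is meant to be sampling noise alone. The weight levels follow
from the signal-to-noise arithmetic of the planted mixtures: at dominant
weight 0.12 the profile contrast is a small multiple of the FC standard
error at 600 timepoints, so assignments are noise-limited there and
noise-free at 2400.

## Seeds and determinism

Every source of randomness descends from one master seed through a fixed
linear-congruential fold (`stage seed = f(master, stage, replicate)`), so
any single subject, bootstrap member or stage can be regenerated in
isolation, and two runs from the same config and inputs are byte-identical.
Results are identical whether members are computed serially or not, because
each member's RNG state is derived, not consumed sequentially.

## Numerical choices and edge cases

* Spherical k-means: kmeans++ initialization on cosine distance, 10
  restarts, 300 iteration cap, objective tolerance 1e-6; empty clusters are
  re-seeded at the worst-fitted point; zero-norm profile rows are
  pre-assigned label 0 and excluded. k may not exceed the number of distinct
  profile directions.
* Hungarian matching: O(k³) potentials algorithm; when one parcellation
  uses fewer labels, the padded assignments carry zero cost.
* Majority-vote ties go to the smallest label id; WTA argmax ties go to the
  earliest lobe in axis order (temporal first).
* All volumes in a run must share grid shape and affine within 1e-4;
  mismatches are hard errors (the package performs no registration).
* Label volumes are validated against their lookup table at construction;
  non-integer label data are rejected unless exactly on integers.

## Known limitations

* The mirror used by the symmetry index is a grid-plane reflection; data
  must be in a midline-aligned template space.
* The WTA lobe merging requires at least two non-empty lobe groups; the
  five-lobe configuration of the default ROI set is the intended use.
* `timepointsBootstrap()` holds the selected subjects' masked series in
  memory; for very long acquisitions, preprocess first and pass reduced
  grids.
* The low-pass filter family/order and the subject-selection rule for
  ROI-ROI matrices are configurable defaults where the original description
  is silent; both are documented above.
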
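---
title: "Methods: quantifying contour variability in multi-sequence MR delineation studies"
author: "contourvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying contour variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When radiotherapy is planned on MR images alone, organ-at-risk (OAR)
contours — here the bladder, rectum, anal canal and both femoral heads —
may be drawn on different MR sequences (T1WI, contrast-enhanced Dixon T1,
T2WI), by different observers, or by an automatic segmentation model.
Before trusting any of these sources interchangeably one has to quantify
three kinds of disagreement over a patient cohort:

* **interobserver** — two delineators, same image;
* **intersequence** — one delineator, different sequences of the same
  patient;
* **automatic vs manual** — a segmentation model against each human.

`contourvar` implements the agreement metrics, the volume statistics and
the three study designs as one pipeline over co-registered binary label
volumes, and ships a synthetic pelvic-phantom generator so that every stage
can be validated end-to-end without patient data.

## Agreement metrics

All geometry is computed in physical millimetres on anisotropic grids
(the default emulates 1 × 1 mm in-plane resolution with 3 mm slices).

**Dice similarity coefficient.** For two contour volumes $A$ and $B$,
$\mathrm{DSC}(A,B) = 2|A \cap B| / (|A| + |B|)$ on voxel counts; 1 means
coincident contours, values above 0.7 are conventionally "good". Two empty
masks leave the DSC undefined: `dsc()` raises an error instead of returning
a silent 0, and the pipeline records such cells as *not available* so they
can never bias a mean ± SD table toward zero.

**Hausdorff distances.** With $X, Y$ the boundary point sets of the two
masks, the directed Hausdorff distance is
$\vec d_H(X,Y) = \max_{x \in X} \min_{y \in Y} \lVert x - y\rVert$,
and the undirected HD is the larger of the two directions. The
95th-percentile variant replaces the maximum over $X$ with the 95th
percentile of the per-point nearest distances, discounting small outlying
mis-segmentations. The symmetrized 95% HD reported by `hd95()` is the
*average* of the two opposite directed 95th-percentile values,
$\tfrac12\big(\vec d_{H,95}(X,Y) + \vec d_{H,95}(Y,X)\big)$: averaging the
two directions is the reading that makes the symmetrization meaningful,
and it is what this package computes throughout.

Three numerical conventions are deliberately pinned down because the
literature often leaves them implicit:

* **Point sets.** Distances are computed between centres of *boundary*
  voxels — foreground voxels with at least one 6-connected background (or
  out-of-grid) neighbour. Computing on full voxel sets instead is exposed
  via `surface = FALSE` on every metric; boundary is the default because
  it matches common 95% HD practice and keeps point sets small enough for
  exact brute-force verification.
* **Percentile rule.** Linear interpolation between the closest order
  statistics (the common default, `stats::quantile` type 7), so
  $q = 100$ reproduces the directed HD exactly.
* **Exactness.** The production path uses an exact anisotropic Euclidean
  distance transform (Felzenszwalb–Huttenlocher, compiled) evaluated at
  boundary voxels; because all points are voxel centres of one shared
  grid, its output is identical — to 10⁻⁹, as the test suite asserts
  against an independent double-loop implementation — to exhaustive
  nearest-neighbour search. Speed never changes a reported value.

Masks are only comparable when they share one grid; `validate_comparable()`
enforces spacing/origin/shape agreement and names the offending field,
which is the symptom of comparing masks from unregistered images. NIfTI
orientation matrices beyond axis-aligned positive scales are rejected at
load time for the same reason, rather than silently reinterpreted.

## Volume statistics

**ICC(2,1).** Volume consistency between raters (observers or sequences)
uses the Shrout–Fleiss intraclass correlation for a two-way random-effects
model with absolute agreement, single measures:
$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$
with $n$ subjects, $k$ raters, and $MS_R, MS_C, MS_E$ the between-subject,
between-rater and residual mean squares. Estimates above 0.75 are flagged
as good agreement; negative estimates are reported as computed, not
clipped. The implementation builds the mean squares from explicit sums of
squares; the test suite checks it against an independent `aov()`-based
decomposition.

A caution that shaped the validation design: with only $k = 2$ raters the
between-rater mean square has a single degree of freedom, so the ICC(2,1)
*estimate* under re-drawn random rater effects is extremely dispersed
(simulation SD ≈ 0.12 at $n = 1000$ under subject variance 4, rater
variance 1, residual variance 1). The recovery simulation therefore fixes
the two rater offsets at $\pm\sqrt{1/2}$ — between-rater variance exactly
1 — under which the estimator concentrates on the population value
$4/(4+1+1) = 2/3$ (SD ≈ 0.015 at $n = 1000$), and additionally averages
20 replicate studies so the check exercises the estimator rather than the
luck of one draw.

**Wilcoxon rank-sum.** Volume differences between two arms are compared
with the two-sided rank-sum test (midranks for ties). The p-value is exact
(null-distribution enumeration) when both samples are small
(`min(n, m) <= 10`) and tie-free, and otherwise uses the normal
approximation with tie and continuity corrections; the result records
which path ran, and `p < 0.05` is flagged as significant. The study design
this mirrors names the rank-sum test even though per-patient volumes are
paired; `wilcoxon_rank_sum(..., paired = TRUE)` exposes the signed-rank
alternative for users who prefer the paired analysis, but the pipeline
follows the rank-sum convention. No multiple-testing correction is
applied, matching that convention as well.

## Study designs

All three designs reduce to one comparison engine: for each patient and
structure, load the two masks named by the comparison arm, compute DSC,
undirected HD, 95% HD and both volumes, and emit one long-format record
per metric with full provenance (patient, structure, design, comparison).
Aggregation happens per (structure, comparison): mean ± SD across patients
(sample SD, denominator $n-1$, formatted to 3 decimals), volume ICC(2,1)
across patients, and a Wilcoxon p on the volumes. Metrics are never pooled
across patients at voxel level. The automatic observer is just another
observer label, which is why `run_auto_vs_manual()` can also report the
automatic model's own intersequence variability with the same code path.
When the two human observers disagree there is no ground truth, so the
automatic contours are reported against *each* human separately.

Missing or empty structures become *not available* records: logged,
excluded from aggregation, reported through a reduced per-cell `n` —
never zero-imputed.

## The synthetic phantom cohort

The generator's purpose is validation: it emulates the *statistical
structure* of a delineation study — per-patient anatomy, per-observer and
per-sequence boundary noise of controllable physical magnitude on
anisotropic grids — not the appearance of MR images.

**Geometry.** Five disjoint structures on a 96 × 96 × 48 grid at
1 × 1 × 3 mm: an ellipsoidal bladder anteriorly (semi-axes 20 × 18 ×
16 mm), a curved rectal tube (radius 11 mm) with a short anal-canal tube
(radius 8 mm) stacked below it along the inferior–superior axis with a
gap, and two lateral spherical femoral heads (radius 13 mm). Organs are
scaled to fit a compact grid, so absolute volumes are below anatomical
values; the relationships that exercise the metrics (disjointness, curved
tubes, small-vs-large structures, 3 mm slice anisotropy) are preserved.
Per-patient realism comes from ±10% size jitter and ±1.5 mm centre jitter
per structure; the generator *verifies* disjointness and in-grid placement
after jitter and raises an error rather than emitting clipped anatomy.

**Perturbation model.** Observer and sequence noise acts on the mask's
signed-distance representation, which makes every component directly
interpretable in millimetres against the measured 95% HD:

* a rigid translation with per-axis SD `translation_sd` (placement
  disagreement), applied by trilinear interpolation of the
  signed-distance field;
* a smooth radial displacement field with pointwise SD `boundary_sd`,
  built from 12 von-Mises–Fisher-shaped bumps with Gaussian coefficients
  over boundary directions (local over/under-inclusion varying smoothly
  around the organ);
* a systematic `dilation_bias` in units of the finest voxel edge
  (an observer's tendency to over- or under-segment). Because distances
  between voxel centres fall on lattice values, an integer dilation is
  inclusive of the corresponding shell while an integer erosion excludes
  it; the implementation nudges the threshold by ±10⁻⁹ voxels to make
  that convention deterministic.

Thresholding the shifted signed distance at the displacement field keeps
the output boundary smooth and topologically simple. A zero model is the
identity by construction.

**Presets.** `paper_like` gives both human observers moderate equal noise
(translation SD 0.8 mm, boundary SD 1.2 mm, R2 with a small +0.3-voxel
dilation bias), makes the contrast-enhanced Dixon sequence 1.5× noisier
than T1WI and T2WI, and gives the automatic observer a larger, sequence-
dependent profile (best on T2WI at 0.7×, worst on T1dixonc at 1.6×).
These choices reproduce the qualitative pattern such studies report —
T1WI–T2WI as the most similar sequence pair, automatic contours closest
to manual on T2WI — while leaving the quantitative scale (mean DSC ≈
0.8–0.9 for large organs, 95% HD of a few mm) in the clinically typical
range. `clean` zeroes everything (an end-to-end identity check);
`heavy_noise` doubles the random components.

**Determinism.** Cohort generation is a pure function of (parameters,
models, master seed). Seeds are split hierarchically per
patient/observer/sequence/structure through an integer hash, so
regenerating with more patients never reshuffles existing ones, and
observer errors are independent across structures — a documented
simplification, since real observers likely correlate errors between
neighbouring organs.

## What passing tests do and do not show

The phantom cohort validates the *software*: metric exactness against
brute force, closed-form sphere geometry, ICC and type-I-error recovery,
monotone response of DSC/95% HD to imposed boundary noise, and the table
shapes and orderings of the three designs. It cannot validate claims about
real anatomy or real observers: phantom shapes are smooth and convex-ish,
noise is radial and independent across structures, and no intensity
information exists, so segmentation difficulty does not vary with tissue
contrast the way it does clinically. Quantitative values from the
`paper_like` preset characterize the preset, not any patient population.

## Problem sizes and tolerances used in validation

The shipped validation suite uses: 100 random mask pairs (≤ 500 boundary
points) for oracle equivalence at 10⁻⁹; spheres of radius 10 mm offset
4 mm rasterized at 0.5 mm (HD within one voxel diagonal, DSC within 2% of
the closed-form lens overlap); 20 replicate ICC studies of 1000 × 2
(tolerance ±0.03 on 2/3); 10 000 null Wilcoxon simulations at n = m = 200
(type-I error within [0.04, 0.06]); 20 seeds per boundary-noise level for
the monotonicity check; and a 29-patient, 3-sequence, 3-observer
`paper_like` cohort — the size of a typical single-centre testing cohort —
for the end-to-end design checks.

## Known limitations

* Only axis-aligned NIfTI grids are supported; oblique acquisitions must
  be resampled upstream (by design — within-patient masks are expected to
  share one grid already).
* `hd95()` requires both masks non-empty; cohort-level code converts that
  error into not-available records, but direct callers must handle it.
* ICC confidence intervals and other ICC forms (1,1), (3,1), (2,k) are
  out of scope, as are Bland–Altman analysis and surface-distance metrics
  beyond the Hausdorff family.
* The rank-sum (rather than signed-rank) convention for paired volumes is
  followed deliberately; both are available at the function level.
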
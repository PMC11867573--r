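# contourvar

Quantifies agreement between 3D organ-at-risk (OAR) delineations in
radiotherapy imaging studies. When pelvic OARs — bladder, rectum, anal
canal, femoral heads — are contoured on different MR sequences (T1WI,
contrast-enhanced Dixon T1, T2WI), by different observers, or by an
automatic segmentation model, the clinical question is whether those
sources agree well enough to be used interchangeably. `contourvar` is for
medical-physics and imaging researchers who need that question answered
reproducibly over a cohort of co-registered binary label volumes (NIfTI),
and for anyone validating segmentation-agreement tooling.

## What it computes

For two contour volumes *A*, *B* on a shared anisotropic grid:

* **Dice similarity coefficient**
  `DSC(A,B) = 2|A ∩ B| / (|A| + |B|)` — 1 means coincident contours,
  values > 0.7 conventionally read as good overlap.
* **Hausdorff distances** on boundary voxel centres (6-connectivity
  surface), in physical mm: the directed distance
  `d⃗_H(X,Y) = max_{x∈X} min_{y∈Y} ‖x − y‖`, the undirected
  `d_H = max{d⃗_H(X,Y), d⃗_H(Y,X)}`, and the symmetrized **95% HD**
  `(d⃗_H,95(X,Y) + d⃗_H,95(Y,X)) / 2`, where `d⃗_H,95` is the 95th
  percentile (linear interpolation) of the per-point nearest distances —
  robust to small outlying mis-segmentations.
* **Volume agreement**: intraclass correlation **ICC(2,1)** (two-way
  random effects, absolute agreement, single measures;
  `ICC = (MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))`, good
  when > 0.75) and the two-sided **Wilcoxon rank-sum** test (exact for
  small tie-free samples, normal approximation with tie/continuity
  corrections otherwise; significant when p < 0.05).

Three cohort designs wrap these per patient and structure, then aggregate
mean ± SD per (structure, comparison) with per-cell ICC and p:
`run_interobserver()` (R1 vs R2 per sequence), `run_intersequence()` (one
observer across sequence pairs) and `run_auto_vs_manual()` (AUTO vs each
human, plus AUTO's own intersequence variability). A deterministic
synthetic pelvic-phantom generator (`generate_cohort()`) produces
multi-patient, multi-observer, multi-sequence cohorts with controllable
boundary noise in mm, so the full pipeline can be exercised and validated
without access-restricted patient data.

## Worked example

Generate a small synthetic cohort with the paper-like noise preset and run
the interobserver design:

```r
library(contourvar)

dir <- file.path(tempdir(), "demo-cohort")
preset <- perturbation_preset("paper_like")
cohort <- generate_cohort(
  n_patients = 4, out_dir = dir, seed = 1,
  observer_models = preset$observer_models,
  sequence_multipliers = preset$sequence_multipliers
)

inter <- run_interobserver(cohort)
inter
#> <variability_result: interobserver> 300 records, 4 patients
#> # A tibble: 30 × 7
#>    metric structure      comparison     n  mean     sd formatted
#>    <chr>  <chr>          <chr>      <int> <dbl>  <dbl> <chr>
#>  1 dsc    bladder        T1WI           4 0.908 0.0287 0.908 ± 0.029
#>  2 hd95   bladder        T1WI           4 2.70  0.860  2.703 ± 0.860
#>  3 dsc    rectum         T1WI           4 0.895 0.0591 0.895 ± 0.059
#>  4 hd95   rectum         T1WI           4 2.42  0.722  2.415 ± 0.722
#>  5 dsc    anal_canal     T1WI           4 0.772 0.0592 0.772 ± 0.059
#>  ...
```

Each row is one cell of the study table: on T1WI the two simulated
observers overlap the bladder with DSC 0.908 ± 0.029 and disagree on its
boundary by 2.7 ± 0.9 mm at the 95th percentile; the small anal canal, as
in real studies, agrees worst. Volume agreement per cell:

```r
dplyr::filter(inter$volume_agreement, comparison == "T1WI")
#> # A tibble: 5 × 7
#>   structure      comparison     n    icc p_value icc_good significant
#>   <chr>          <chr>      <int>  <dbl>   <dbl> <lgl>    <lgl>
#> 1 bladder        T1WI           4  0.921   0.886 TRUE     FALSE
#> 2 rectum         T1WI           4  0.733   1     FALSE    FALSE
#> 3 anal_canal     T1WI           4 -0.283   0.886 FALSE    FALSE
#> 4 femoral_head_L T1WI           4  0.884   0.686 TRUE     FALSE
#> 5 femoral_head_R T1WI           4  0.857   0.486 TRUE     FALSE
```

The bladder's volumes correlate strongly between observers (ICC 0.92,
"good" by the > 0.75 convention) while the anal canal's do not — with only
4 patients the ICC is noisy; a realistic cohort uses 29. `glance(inter)`
gives the one-row overview (here mean DSC 0.828, mean 95% HD 3.42 mm over
all 300 records), `tidy(inter)` the per-patient records,
`autoplot(inter)` the standard boxplot figure, and
`write_report(list(inter), out_dir)` the CSV/JSON report bundle.

A command-line wrapper with `synth` and `run` subcommands is installed at
`inst/cli/contourvar`.

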
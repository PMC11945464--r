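---
title: "Voxel-wise normative R1 modeling and subject-specific deviation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise normative R1 modeling and subject-specific deviation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxnorm)
```

## The problem

Chronic occupational exposure to airborne manganese — welding being the
canonical setting — leads to Mn deposition in the brain, classically in the
globus pallidus (GP) but, at higher exposures, spreading through white
matter (WM). Mn is paramagnetic: it shortens the longitudinal relaxation
time T1, i.e. raises the relaxation rate R1 = 1/T1. Group comparisons of R1
maps can show where welders on average accumulate Mn, but individual
exposure and toxicokinetics vary enormously, so a group map says little
about any one worker. `relaxnorm` implements the complementary,
subject-specific route: build a voxel-wise *normative* model of R1 from a
healthy reference cohort, then score each individual voxel-by-voxel against
that norm.

The package assumes its inputs are already spatially normalized: all R1
maps and tissue probability maps live on one common grid
(`assert_shared_grid()` enforces this). Registration, segmentation and
skull-stripping are upstream of this package and out of its scope.

## The model

### R1 estimation from two flip angles

A spoiled gradient-echo (SPGR) acquisition at steady state has magnitude

$$S(\alpha) = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha}, \qquad
E_1 = e^{-\mathrm{TR}\cdot R_1}.$$

With two flip angles the standard linearization
$S/\sin\alpha = E_1 \cdot S/\tan\alpha + M_0(1 - E_1)$ turns the fit into a
two-point slope, solved in closed form per voxel (`fit_vfa_r1()`). Defaults
follow a typical 3 T protocol: TR 6.36 ms, flip angles 3° and 17°. Voxels
whose slope is outside (0, 1) — zero signal, pure noise — get an `NA`
marker and behave as outside-mask downstream. Nominal flip angles are
trusted; transmit-field (B1) correction is a scanner-side preprocessing
step and is not modeled, which is also why the synthetic phantoms carry no
B1 inhomogeneity.

### The normative atlas

Within an analysis mask, each voxel $r$ of the healthy cohort is modeled by
ordinary least squares on centered age $a = \mathrm{age} - \bar{\mathrm{age}}$:

$$E\{R_1(r)\} = \beta_0(r) + \beta_{age}(r)\, a + \beta_{age^2}(r)\, a^2 .$$

The quadratic term accommodates the well-documented inverted-U trajectory
of R1 over adult life. Ages are whole years; the centering age is stored at
full precision (display conventions round it, the model should not). The
residual standard deviation is kept as the RMSE map,

$$\mathrm{RMSE}(r) = \sqrt{\mathrm{SSR}(r) / (n - p)},$$

with $p = 3$ coefficients; a `rmse_denominator = "n"` switch gives the
strict root-mean-square convention, and the difference is a known constant
factor $\sqrt{(n-p)/n}$. The reference cohort here is male-only, so no sex
term is included, but `fit_atlas()` accepts extra covariate columns for
mixed cohorts.

The analysis mask is the thresholded average of the cohort's WM probability
maps: a voxel enters iff the mean probability *strictly* exceeds 0.5
(`build_wm_mask()`). At 50% this keeps deep, well-registered structures —
including the GP, which matters because it is the primary Mn target — while
excluding cortex, where residual misalignment blends GM and WM and inflates
the residual error beyond usefulness for single-subject inference. Voxels
whose fit is degenerate (zero residual variance, e.g. on synthetic
noise-free data, or any subject invalid there) are pruned from the mask:
the deviation score divides by RMSE, and a zero or undefined denominator is
not a statement about the subject.

### Deviation maps and cluster correction

A subject with R1 map $R_1(r)$ and age $a^*$ is scored per voxel as

$$z(r) = \frac{R_1(r) - E\{R_1(r);\, a^*\}}{\mathrm{RMSE}(r)},$$

(`compute_zmap()`). Isolated high-z voxels are expected by chance, so the
map is cluster-corrected (`cluster_correct()`): voxels with $z > 6$
(strict, one-sided — Mn only raises R1; a two-sided mode exists behind a
flag) are grouped into connected components, and components smaller than
100 voxels are discarded ("retain iff size ≥ 100"). Connectivity defaults
to 26-neighbor, with 6 and 18 selectable; border-touching components are
ordinary components. Retained clusters are labeled 1..K by decreasing size,
ties broken by smallest linear voxel index, so reports are reproducible.
Cluster tables (`summarize_clusters()`) report size, peak z, peak location
and centroid in 0-based voxel coordinates, following the NIfTI convention.

### False-positive validation

`kfold_fpr()` estimates how often the method flags a *healthy* voxel:
controls are dealt into k = 10 near-equal folds (deterministic given a
seed), the atlas is refitted without each fold, and each held-out control
is scored. FPR is defined voxel-wise — the fraction of in-mask voxels
flagged per held-out subject, averaged over subjects — which is the most
literal reading of a WM false-positive rate; a cluster-filtered counting
mode is also provided because published FPR figures for this family of
methods do not always state whether extent filtering preceded counting.
The validation threshold is deliberately a separate, configurable setting
(default z > 2) rather than the detection threshold: at z > 6 with extent
filtering the FPR on Gaussian nulls is essentially zero and measures
nothing about calibration.

### Exposure subgrouping

`classify_exposure()` implements the cumulative-exposure-index rule used to
contextualize the maps: a welder whose CEI over the past three months
exceeds 0.04 mg/m³·yr is high-exposure (HEX), otherwise low-exposure (LEX).
The inequality is strict — "exceeding" — so a welder at exactly 0.04 is
LEX, consistent with the published grouping of the ten reference welders
(shipped as `inst/extdata/welder_exposure.csv`); applying the rule to that
table yields the published 5 HEX / 5 LEX split.

## The synthetic phantom

No study MRI data are available, so the package carries a generator
(`phantom_spec()`, `generate_cohort()`) that produces pre-aligned cohorts
with exactly the statistical structure the analysis assumes:

* **Geometry** — nested ellipsoids: background, a GM shell, a WM core, and
  two spherical GP blobs embedded in the core. This is deliberately
  minimal; it gives connected tissue regions and a WM∪GP mask, nothing
  anatomical beyond that.
* **Baselines** — WM 1.07 s⁻¹ and GP 1.10 s⁻¹ at the reference age of 39
  years, matching the reference cohort's reported frontal-WM and GP
  values; GM 0.65 s⁻¹, a typical 3 T cortical value (the reference
  methodology excludes cortex, so this choice only shapes the mask edge).
* **Age dependence** — a global quadratic law with defaults
  $\beta_{age} = 0.002$ s⁻¹/yr and $\beta_{age^2} = -2\times10^{-4}$
  s⁻¹/yr², i.e. an inverted U peaking in mid-life with roughly a 0.1 s⁻¹
  swing over ages 20–61. No published coefficient values exist for this
  cohort; these magnitudes are chosen once as physiologically plausible and
  are what the atlas must recover, not a claim about real aging.
* **Noise** — per-subject Gaussian residual fields, optionally smoothed
  with a configurable FWHM (default 3 mm) to mimic the spatial correlation
  that registration and partial voluming induce in real residuals. The
  smoothed field is renormalized so its *marginal* per-voxel SD equals
  `noise_sd` (default 0.15 s⁻¹, the reported WM RMSE) regardless of FWHM —
  otherwise the meaning of `noise_sd` would silently change with the
  smoothing setting. Entirely unsmoothed noise makes cluster correction
  trivially powerful and is used where analytic Gaussian tails are the
  reference.
* **Lesions** — welders receive 0–3 spherical additive R1 elevations in
  WM/GP with $\Delta R_1 \in [0.3, 1.2]$ s⁻¹ and radius 2.5–4.5 mm. No
  published lesion magnitudes in s⁻¹ exist; the range spans barely
  detectable (2σ) to unmistakable (8σ) elevations, and the 0-lesion case
  mirrors the observation that some highly exposed welders show no excess
  accumulation. Ages are whole years, uniform over (20, 61), the reference
  control range.

Everything is deterministic given the spec seed: identical specs produce
bit-identical cohorts, and the pipeline's manifests hash-match across
reruns.

What the phantom does *not* emulate: anatomy, acquisition physics (k-space,
B1), registration failure modes, and spatially varying residual SD (the
real GP shows a smaller RMSE than WM; the generator's noise is globally
calibrated). Tests passing on phantoms therefore validate the *estimators
and their calibration under the stated model*, not robustness to real-data
violations of it.

## Numerical choices and edge cases

* Volumes are promoted to 64-bit floats on read; NIfTI files are written as
  float32. All voxel-wise fits go through one QR decomposition of the
  n × 3 design shared across voxels.
* The atlas fit requires ≥ 4 subjects and ≥ 3 distinct ages (the quadratic
  design is rank-deficient otherwise) and refuses rank-deficient designs
  rather than silently dropping terms.
* Connected components use iterative minimum-label propagation; labels are
  provably the per-component minimum linear index at convergence, which is
  what makes the tie-break deterministic. The test suite checks it against
  an independent breadth-first flood fill at all three connectivities.
* Cluster thresholding is strict (`z > t`), matching the strict reading of
  both the z cut and the probability cut in the mask rule.
* `predict()` warns (not errors) more than 60 years from the reference age:
  extrapolation is statistically dubious but occasionally intentional.

### Small-sample inflation of held-out z-scores

One property of the method is worth stating precisely because it is easy to
mistake for a bug. For a control *not* used in fitting, the z-score at a
voxel is a residual divided by an estimated SD:
$z/\sqrt{1+h} \sim t_{n-p}$, where $h$ is the regression leverage of the
subject's age. Pooled over voxels and subjects, the SD of held-out null
z-scores is therefore not 1 but

$$\sqrt{(1 + \bar h)\,\frac{n-p}{n-p-2}} \;\approx\; 1.12
\quad\text{at } n = 25,\ p = 3,$$

and the package's calibration tests assert agreement with this t-based
prediction rather than with an exact standard normal. The inflation decays
like $1/n$; at the validation threshold z = 2 the same algebra predicts a
held-out exceedance slightly above the Gaussian tail
$1-\Phi(2) = 2.28\%$ (about 2.7% for a k = 10 split of 80 controls), which
is what the cross-validated FPR reproduces. Practically: with a 25-subject
reference cohort, single-subject z maps run a little hot, uniformly; the
z > 6 detection rule is far enough out that this has no effect on detection
specificity, but percentile-level interpretations of mid-range z values
should use the t calibration above.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run on grids of 16³–40³ voxels
with cohorts of 8–200 subjects: 32³ for the 25-control atlas
characterization and the n = 200 RMSE-recovery study, 28³ (unsmoothed
noise) for null calibration (25 fit / 25 held out) and the k = 10
cross-validated FPR over 80 controls, and 40 seeded 40³ runs for lesion
detection at $\Delta R_1 = 8\sigma$ with ~270-voxel lesions. These sizes
were chosen so that every Monte-Carlo quantity has comfortable sampling
error at desk scale; all of them are plain parameters, and larger grids or
cohorts change nothing but runtime.

## Limitations

* The atlas is only as good as the registration feeding it; the package
  checks grid identity, not registration quality.
* With a 25-subject reference cohort the RMSE map itself is noisy
  (χ² with 22 df per voxel, ≈ 15% relative SD), which is the dominant
  source of the z-score inflation quantified above.
* The published mean cross-validated FPR of ~7% for this methodology on
  real data is not reproducible here — it depends on the (unreleased) real
  cohort and on an unspecified flagging threshold — and serves only as
  context; on synthetic Gaussian nulls the package's FPR matches the
  analytic t/Gaussian tails instead.
* GM-cortex and subcortical GM structures other than the GP are outside
  the analysis mask by construction, as in the source methodology; absence
  of flagged clusters there is absence of evidence, not evidence of
  absence.
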
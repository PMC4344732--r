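---
title: "Estimating intracranial volume from sparse slice areas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intracranial volume from sparse slice areas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icvsparse)
library(dplyr)
```

## The problem

Intracranial volume (ICV) is the standard proxy for premorbid brain size in
volumetric neuroimaging, used to normalise whole-brain and regional volumes
across subjects. Segmenting the whole intracranial vault by hand on a 1 mm
isotropic MRI takes hours per scan, so a common shortcut is to segment only
every *n*-th slice and reconstruct the volume from the resulting sequence of
intracranial areas (ICAs). This package implements that estimator — with
piecewise constant, piecewise linear, and cubic spline interpolation of the
sampled areas — together with the full machinery needed to quantify how much
validity is lost as the linear spacing *n* grows, and a calibrated phantom
generator so the whole pipeline can be exercised and tested without any MRI
data.

## The estimator

A subject's segmentation is reduced to an area profile: the ICA
$A_i \ge 0$ (mm²) of each 1 mm slice $i$ along one slicing orientation
(sagittal, coronal, or transversal). Sampling every $n$ mm admits exactly
$n$ phase positions ("offsets"): the first sampled slice must fall within one
spacing of the outermost positive-area slice on the designated starting side
(anterior for coronal, superior for transversal, the low-index end for
sagittal; profiles are stored in those directions). The $n$ offset subsamples
partition the support, a property the tests verify by brute force for all
spacings 1–50.

Given the subsample $A_{k}, A_{k+n}, A_{k+2n}, \dots$:

* **piecewise constant**: $\hat V = n \sum_j A_{k+jn}$ — each sampled area
  stands in for a slab of thickness $n$;
* **piecewise linear**: the trapezoidal integral through the sampled points
  plus two zero-area anchors;
* **cubic spline**: the exact integral of the $C^2$ not-a-knot cubic spline
  through the same padded points.

The zero anchors are placed one voxel beyond the outermost positive-area
slice on each side — the first empty slices, i.e. where the vault has ended.
Whether the anchors belong on the last occupied slices or one beyond is a
genuinely open choice; one-beyond was adopted because a slice with zero area
is by definition outside the vault, and the padding position is switchable in
`pad_zeros()` only through the profile support, keeping the convention in one
place. At full density ($n = 1$) both the constant and the padded-linear
estimator reproduce the slice-sum volume *exactly* (the trapezoid sum
telescopes), which the tests assert to machine precision.

### Numerical choices

The spline uses the **not-a-knot** end condition — third-derivative
continuity across the first and last interior knots — matching the default of
the MATLAB `spline` function that historically defined this computation. The
implementation solves the second-derivative tridiagonal system with two
corner rows and integrates the explicit per-segment cubics, so the volume
carries no quadrature error; tests pin it against an independent not-a-knot
implementation on fixed knot sets, against the cubic-polynomial reproduction
property (which distinguishes not-a-knot from natural end conditions), and
against 0.01 mm composite Simpson quadrature of the same spline.

Degenerate subsamples at extreme spacings degrade gracefully: with three
points (two pads and one ICA) the interpolant is the unique parabola, with
two points the chord. The spline is *not* clamped at zero: near the steep
vault ends it can undershoot, and those negative lobes integrate as-is,
because that is what the plainly-implemented spline pipeline produces; a
warning of class `icvsparse_negative_spline` flags any subsample whose
interpolant dips below zero so users can audit coarse-spacing estimates.

## The validity evaluation

Validity is a property of a *spacing*, not of one lucky offset. With 62
subjects and $n$ offsets each, a cohort-level comparison requires choosing
one offset per subject — an $n^{62}$ combination space — so
`evaluate_validity()` draws 2000 random combinations per (spacing,
orientation) setting, with replacement, and reuses the same combinations
across the three interpolation methods so method contrasts are not
confounded by sampling noise. Per combination it computes, against the true
volumes:

* **ICC(A,1)** — the single-measure absolute-agreement intraclass
  correlation from the two-way ANOVA with subjects as targets and
  {truth, estimate} as raters,
  $\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E)}$;
  the between-rater mean square $MS_C$ makes it sensitive to systematic
  bias, unlike Pearson correlation (for single-measure absolute agreement
  the two-way random and mixed models coincide, so both flags are accepted);
* **Pearson correlation**;
* the **generalized Jaccard index** $\sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$;
* signed **percentage errors**, pooled over every member estimate of every
  combination (pooling, rather than taking each combination's maximum,
  avoids letting single extremes dominate the curves).

Each metric's distribution is summarised by 5th/25th/50th/75th/95th
percentile curves (linear interpolation between order statistics,
`quantile` type 7 — the differences between quantile definitions are
negligible at 2000 draws). Degenerate metric values are recorded as missing
with a warning rather than dropped, and an ICC whose denominator vanishes is
an error in the scalar API: silent perfection masks bugs.

A master seed expands into a deterministic substream per (spacing,
orientation), so any single setting can be reproduced on its own regardless
of which grid it was requested in.

Finally, `compare_interpolators()` runs the paired contrast: per subject,
the mean absolute percentage error (MAPE) over all $n$ offsets for the
piecewise constant and the spline estimator, compared with a paired
Student's t-test per spacing and orientation; positive mean differences
mean the spline improves on the constant rule.

## The phantom cohort

`generate_cohort()` emulates the study population the package is calibrated
to: 62 subjects (39 female, 23 male), gender-specific ICV distributions
(female 1416955 ± 91678 mm³, male 1658268 ± 115535 mm³, truncated at ±4 sd
to exclude nonphysical draws while leaving the moments essentially
unchanged), and a sagittal extent of 136 ± 5 one-mm slices. Coronal and
transversal extents are scaled from the sagittal one by fixed aspect ratios
(1.25 and 0.95), since only sagittal slice counts are available as
population statistics; the three orientations share each subject's target
volume exactly, mirroring one segmentation sliced three ways.

Each profile is the base law
$A(t) = A_{\text{peak}} (1 - |2t/L - 1|^p)^{1/q}$ times a multiplicative
perturbation $1 + \iota\, s(t)$, where $s(t)$ is a sum of up to three
low-frequency sinusoids with random amplitudes and phases normalised so
$|s| \le 1$, and the result is rescaled so the slice sum hits the target
volume exactly. The defaults $p = 2, q = 1$ give the area law of an
ellipsoid — the canonical head-phantom geometry, with finite end slopes;
$p = q = 2$ gives a semi-elliptical area curve instead. Because the
perturbation is multiplicative and $\iota < 1$, areas stay positive and the
support contiguous by construction.

The irregularity defaults ($\iota$ = 0.03 sagittal and coronal, 0.12
transversal) were calibrated once so the percentile curves of the synthetic
cohort qualitatively reproduce what is seen on real vaults: high validity at
small spacings for every method and orientation, smooth degradation of the
spline for sagittal/coronal areas, systematic underestimation by the
trapezoidal rule that grows with spacing, and noticeably worse spline
behavior transversally, where the skull base makes real area sequences least
smooth and the spline's smoothness assumption misfires.

What the phantoms deliberately do **not** model: rater variability (the
mixed-model ICC flag exists for users with real re-segmentation data), head
tilt, anatomical asymmetry, or any skull/dura microstructure. Passing tests
on phantoms therefore demonstrate the correctness and internal behavior of
the estimators and metrics under realistic volume, extent and smoothness
statistics — not segmentation difficulty on real images.

`profile_to_mask()` closes the loop for the 3D path: it voxelizes a sagittal
profile into stacked elliptical cross-sections (an ellipsoid for the default
shape), and `area_profile()` on the result round-trips the input within
voxelization error, which ties the mask module to the profile module in the
tests.

## Image conditioning

The preprocessing module reproduces the display-conditioning chain applied
before manual segmentation: a robust per-scan brightness measure (mean over
the central 80% of the representable tonal range $[0, B-1]$, $B = 4096$ for
12-bit data — "tonal range" is read as the representable range, not the
per-image min–max, so the band is consistent across scans), an additive
brightness match to the cohort grand mean (iterated, because shifting moves
voxels across the band boundary; additive was chosen as the plain reading of
a brightness adjustment, and the tail question — 10% per side, not 10%
total — likewise takes the plain reading), a tail-compressing contrast
stretch, the gamma correction $y = B (x/B)^{0.8}$, and separable trilinear
resampling to a 1 mm isotropic grid (exact on affine intensity fields,
volume-conserving within 2% on smooth masks of ≥ 10⁵ voxels). These steps
condition what a rater sees; they do not touch the area arithmetic, and the
estimation pipeline runs without them.

## Problem sizes used in tests

The shipped tests run the full Monte-Carlo on the default 62-subject cohort
at spacings {10, 24, 50} with 2000 combinations — the settings at which the
method's headline figures live — and exercise the full 2–50 mm grid through
targeted property checks (offset partitioning, reversal symmetry, oracle
equivalences) rather than by evaluating all 441 settings, which is the
package's chosen balance between coverage and a test suite that runs in
about a minute. `evaluate_validity()` itself accepts the full grid.

## Known limitations

* Profiles must live on a regular grid with integer-mm spacings; the 1 mm
  isotropic resample is assumed upstream, as in the source protocol.
* The combination evaluation requires every subject to support the
  requested spacing; a spacing exceeding the shortest support is an error
  rather than a silent subset.
* ICC confidence intervals are not computed — the Monte-Carlo percentile
  curves are the uncertainty statement used here.
* Phantom realism is statistical, not anatomical (see above); absolute
  error levels on real vaults with rater noise will be higher, and the
  intra-/inter-rater contribution must be assessed on real re-segmentations.
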
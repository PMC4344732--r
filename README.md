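# icvsparse

Estimation of intracranial volume (ICV) from sparse, linearly spaced
cross-sectional areas, with a full Monte-Carlo validity evaluation.

Manual segmentation of the whole intracranial vault on a 1 mm isotropic MRI
takes hours per scan, so volumetric studies routinely segment only every
*n*-th slice and reconstruct the volume from the resulting intracranial
areas (ICAs). `icvsparse` is for neuroimaging researchers who use — or want
to audit — that shortcut. It provides:

* the estimator itself, under three interpolation schemes. For a subsample
  of areas `A_k, A_{k+n}, A_{k+2n}, ...` taken every `n` mm at offset `k`:
  - piecewise constant: `V = n * sum_j A_{k+jn}`,
  - piecewise linear: the trapezoidal integral through the sampled areas
    plus zero-area anchors one voxel beyond each end of the vault,
  - cubic spline: the exact analytic integral of the not-a-knot C² cubic
    spline through the same padded points;
* the validity machinery: for each spacing and slicing orientation, all `n`
  offset estimates per subject, random offset combinations across the
  cohort (the combination space holds `n^m` members for `m` subjects), and
  per-combination ICC(A,1) — the single-measure absolute-agreement
  intraclass correlation, `(MS_R - MS_E) / (MS_R + MS_E + (2/n)(MS_C - MS_E))`
  — Pearson correlation, generalized Jaccard index
  `sum(min(x_i, y_i)) / sum(max(x_i, y_i))`, and pooled signed percentage
  errors, summarised as 5th–95th percentile curves, plus a paired t-test of
  per-subject mean absolute percentage errors (constant vs spline);
* slice-area extraction and exact reference volumes from 3D binary masks
  (NIfTI in/out), display conditioning for raw scans (robust brightness
  matching, contrast stretch, gamma correction `y = B (x/B)^0.8`, trilinear
  1 mm resampling);
* a calibrated phantom-cohort generator (62 subjects, 39 female / 23 male,
  gender-specific ICV distributions, 136 ± 5 sagittal slices) so everything
  above runs and is tested without MRI data.

## Worked example

Generate one smooth 1.5 L phantom profile and estimate its volume from
slices 24 mm apart, at every possible offset:

```r
library(icvsparse)
library(dplyr)

p <- generate_profile(1.5e6, extent = 136, irregularity = 0.03, seed = 7)
p
#> <icv_profile> sagittal, subject phantom, 136 slices @ 1 mm, volume 1500000 mm^3

est <- estimate_icv(p, spacing = 24)
est
#> # A tibble: 72 × 6
#>   subject_id orientation method   spacing_mm offset value_mm3
#>   <chr>      <chr>       <chr>         <dbl>  <int>     <dbl>
#> 1 phantom    sagittal    constant         24      0  1487557.
#> 2 phantom    sagittal    linear           24      0  1457964.
#> 3 phantom    sagittal    spline           24      0  1490231.
#> # ...

est %>%
  group_by(method) %>%
  summarise(mean_err_pct = mean(100 * (value_mm3 - 1.5e6) / 1.5e6),
            sd_err_pct   = sd(100 * (value_mm3 - 1.5e6) / 1.5e6))
#>   method   mean_err_pct sd_err_pct
#> 1 constant    -1.93e-15     0.785
#> 2 linear      -2.70e+00     0.0747
#> 3 spline      -1.55e-03     0.287
```

Even from only six slices, all three estimators land within a few percent;
the constant rule is unbiased across offsets but wobbles with the phase, the
trapezoidal rule is steady but systematically low (chords under a concave
profile), and the spline is both nearly unbiased and steady.

The cohort-level question — how much validity does a given spacing cost? —
is answered by the Monte-Carlo evaluation:

```r
cohort <- generate_cohort(population_spec(n_female = 6, n_male = 4, seed = 2))
ev <- evaluate_validity(cohort, spacings = c(10, 30),
                        orientations = "sagittal", count = 500, seed = 2)

tidy(ev) %>% filter(metric == "icc", percentile == 5)
#>   spacing_mm orientation method   metric percentile value
#> 1         10 sagittal    constant icc             5 1.000
#> 2         10 sagittal    linear   icc             5 0.999
#> 3         10 sagittal    spline   icc             5 1.000
#> 4         30 sagittal    constant icc             5 0.992
#> 5         30 sagittal    linear   icc             5 0.942
#> 6         30 sagittal    spline   icc             5 0.999
```

At 10 mm spacing the interpolation method barely matters — the 5th
percentile of the ICC distribution stays at or above 0.999 for all three.
At 30 mm the spline still holds an ICC of 0.999 while the trapezoidal
rule's bias has pulled its absolute agreement down to 0.94.
`compare_interpolators(cohort, spacing = 30)` formalises the contrast
(here: mean per-subject MAPE 1.04% constant vs 0.25% spline).
`autoplot(ev)` draws the percentile curves,
`plot_interpolator_comparison(ev)` the paired differences, and
`write_validity(ev, dir)` exports the long-format CSVs plus a JSON run
manifest.

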
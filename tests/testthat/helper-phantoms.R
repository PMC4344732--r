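# Fixtures built in code: analytic ellipsoids and small phantom cohorts.

# Voxelized ellipsoid mask, semi-axes (a, b, c) mm at `vox` mm voxels,
# voxel centers at (i-1)*vox.
make_ellipsoid_mask <- function(a = 60, b = 70, c = 80, vox = 1,
                                subject_id = "ellipsoid") {
  xs <- seq(-a, a, by = vox)
  ys <- seq(-b, b, by = vox)
  zs <- seq(-c, c, by = vox)
  inside <- outer(
    outer((xs / a)^2, (ys / b)^2, `+`), (zs / c)^2, `+`
  ) <= 1
  voxel_mask(inside, voxel_size = vox, subject_id = subject_id)
}

# Analytic elliptical-cross-section area profile of that ellipsoid along the
# first axis: A(x) = pi*b*c*(1 - x^2/a^2).
make_ellipse_profile <- function(a = 60, b = 70, c = 80,
                                 orientation = "sagittal",
                                 subject_id = "ellipse") {
  pos <- 0:(2 * a)
  x <- pos - a
  areas <- pmax(0, pi * b * c * (1 - (x / a)^2))
  as_area_profile(
    data.frame(position_mm = pos, area_mm2 = areas),
    orientation = orientation, subject_id = subject_id
  )
}

# Small smooth phantom cohort for validity tests.
make_tiny_cohort <- function(n_female = 3, n_male = 2, seed = 11) {
  generate_cohort(population_spec(
    n_female = n_female, n_male = n_male, seed = seed
  ))
}

# Composite Simpson quadrature of a function on [lo, hi] at step ~h.
simpson <- function(f, lo, hi, h = 0.01) {
  n <- max(2, 2 * ceiling((hi - lo) / (2 * h)))
  x <- seq(lo, hi, length.out = n + 1)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f(x)) * (hi - lo) / (3 * n)
}
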
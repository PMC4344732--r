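#' Population parameters of the phantom cohort
#'
#' Defaults describe the study population the package is calibrated to:
#' 62 memory-clinic participants (39 female, 23 male) with gender-specific
#' intracranial volumes (female 1416955 +/- 91678 mm^3, male
#' 1658268 +/- 115535 mm^3) and a sagittal vault extent of 136 +/- 5 one-mm
#' slices. Coronal and transversal extents are scaled from the sagittal one
#' by fixed anatomical aspect ratios. The profile shape follows
#' `A(t) = A_peak * (1 - |2t/L - 1|^p)^(1/q)` modulated by a smooth random
#' perturbation; with the default `p = 2, q = 1` the base shape is the area
#' law of an ellipsoid, and `p = q = 2` gives an elliptical (semi-ellipse)
#' area curve. Irregularity — the relative amplitude of the low-frequency
#' perturbation — is higher transversally, where real vault areas are least
#' smooth because of the skull base.
#'
#' @param n_female,n_male Cohort composition.
#' @param female_mean,female_sd,male_mean,male_sd Target ICV distribution in
#'   mm^3 per gender.
#' @param extent_mean,extent_sd Sagittal support length in 1 mm slices.
#' @param coronal_ratio,transversal_ratio Extent of the other orientations
#'   relative to the sagittal extent.
#' @param shape_power Exponent `p` of the base area law (crown flatness).
#' @param shape_root Exponent `q`; the base law is `(1 - |u|^p)^(1/q)`.
#' @param irregularity Named numeric: relative perturbation amplitude per
#'   orientation, each in `[0, 1)`.
#' @param seed Integer seed driving the whole cohort draw.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_female = 39, n_male = 23,
                            female_mean = 1416955, female_sd = 91678,
                            male_mean = 1658268, male_sd = 115535,
                            extent_mean = 136, extent_sd = 5,
                            coronal_ratio = 1.25, transversal_ratio = 0.95,
                            shape_power = 2, shape_root = 1,
                            irregularity = c(sagittal = 0.03, coronal = 0.03,
                                             transversal = 0.12),
                            seed = 1L) {
  if (n_female < 0 || n_male < 0 || n_female + n_male < 2) {
    abort("need at least 2 subjects in total.")
  }
  if (any(c(female_sd, male_sd) <= 0)) abort("volume sds must be > 0.")
  if (extent_mean < 20) abort("`extent_mean` must be >= 20 slices.")
  if (!all(ORIENTATIONS %in% names(irregularity))) {
    abort("`irregularity` needs entries sagittal, coronal, transversal.")
  }
  if (any(irregularity < 0) || any(irregularity >= 1)) {
    abort("`irregularity` values must lie in [0, 1).")
  }
  structure(
    list(
      n_female = as.integer(n_female), n_male = as.integer(n_male),
      female_mean = female_mean, female_sd = female_sd,
      male_mean = male_mean, male_sd = male_sd,
      extent_mean = extent_mean, extent_sd = extent_sd,
      coronal_ratio = coronal_ratio, transversal_ratio = transversal_ratio,
      shape_power = shape_power, shape_root = shape_root,
      irregularity = irregularity[ORIENTATIONS],
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<population_spec> %d F + %d M, ICV F %.0f+/-%.0f M %.0f+/-%.0f mm^3,\n",
      "  sagittal extent %g+/-%g slices, shape (p=%g, q=%g), irregularity ",
      "%s, seed %d\n"
    ),
    x$n_female, x$n_male, x$female_mean, x$female_sd, x$male_mean, x$male_sd,
    x$extent_mean, x$extent_sd, x$shape_power, x$shape_root,
    paste(sprintf("%s=%.2f", substr(ORIENTATIONS, 1, 3), x$irregularity),
          collapse = " "),
    x$seed
  ))
  invisible(x)
}

#' Generate one phantom area profile
#'
#' Evaluates the base law `(1 - |2t/L - 1|^p)^(1/q)` at the slice centers of
#' a support of `extent` one-mm slices, multiplies it by
#' `1 + irregularity * s(t)` where `s(t)` is a sum of at most three
#' low-frequency sinusoids with random amplitudes and phases (normalised so
#' `|s| <= 1`), and rescales the areas so the slice sum equals
#' `target_volume` exactly. The perturbation is multiplicative, so areas
#' stay positive and the support contiguous for any `irregularity < 1`.
#'
#' The function draws from R's global RNG unless `seed` is given; two calls
#' from the same RNG state produce identical profiles.
#'
#' @param target_volume Volume the slice sum must reproduce, mm^3.
#' @param extent Support length in 1 mm slices, `>= 20`.
#' @param shape_power,shape_root Base-law exponents (see [population_spec()]).
#' @param irregularity Relative perturbation amplitude in `[0, 1)`.
#' @param n_harmonics Number of sinusoids in the perturbation (at most 3).
#' @param orientation,subject_id Metadata for the resulting profile.
#' @param seed Optional seed for an isolated draw.
#' @return An `icv_profile` on a 1 mm grid.
#' @export
generate_profile <- function(target_volume, extent,
                             shape_power = 2, shape_root = 1,
                             irregularity = 0, n_harmonics = 3,
                             orientation = "sagittal",
                             subject_id = "phantom", seed = NULL) {
  if (target_volume <= 0) abort("`target_volume` must be > 0.")
  if (extent < 20) abort("`extent` must be >= 20 slices.")
  if (irregularity < 0 || irregularity >= 1) {
    abort("`irregularity` must lie in [0, 1).")
  }
  n_harmonics <- min(as.integer(n_harmonics), 3L)
  build <- function() {
    t_rel <- (seq_len(extent) - 0.5) / extent
    u <- abs(2 * t_rel - 1)
    base <- (1 - u^shape_power)^(1 / shape_root)
    if (irregularity > 0 && n_harmonics > 0) {
      amp <- runif(n_harmonics, 0.5, 1)
      amp <- amp / sum(amp)
      phase <- runif(n_harmonics, 0, 2 * pi)
      s <- rowSums(vapply(seq_len(n_harmonics), function(j) {
        amp[j] * sin(2 * pi * j * t_rel + phase[j])
      }, numeric(extent)))
      base <- base * (1 + irregularity * s)
    }
    if (all(base <= 0)) abort("degenerate shape: no positive areas.")
    areas <- base * (target_volume / sum(base))
    new_area_profile(
      positions = (seq_len(extent) - 1), areas = areas,
      orientation = orientation, subject_id = subject_id, voxel_size = 1
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a phantom cohort with three consistent profiles per subject
#'
#' Draws each subject's target ICV from its gender's normal distribution
#' (truncated at +/- 4 sd to exclude nonphysical volumes while leaving the
#' moments essentially unchanged), a sagittal extent from the slice-count
#' distribution, and coronal/transversal extents by the fixed aspect
#' ratios. The three orientations' profiles share the subject's target
#' volume exactly, mirroring a single segmentation sliced three ways.
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per subject and orientation: `subject_id`,
#'   `sex` (`"F"`/`"M"`), `true_volume_mm3`, `orientation`, `extent`, and
#'   list-column `profile`; the spec is attached as attribute `"spec"`.
#' @examples
#' cohort <- generate_cohort(population_spec(n_female = 3, n_male = 2, seed = 7))
#' dplyr::count(cohort, sex)
#' @export
generate_cohort <- function(spec = population_spec()) {
  if (!inherits(spec, "population_spec")) {
    abort("`spec` must be a population_spec().")
  }
  withr::with_seed(spec$seed, {
    n <- spec$n_female + spec$n_male
    sex <- rep(c("F", "M"), c(spec$n_female, spec$n_male))
    mu <- ifelse(sex == "F", spec$female_mean, spec$male_mean)
    sdv <- ifelse(sex == "F", spec$female_sd, spec$male_sd)
    vol <- rnorm_truncated(n, mu, sdv, lower = mu - 4 * sdv,
                           upper = mu + 4 * sdv)
    sag_extent <- pmax(20L, as.integer(round(rnorm(n, spec$extent_mean,
                                                   spec$extent_sd))))
    ids <- sprintf("phantom%02d", seq_len(n))
    rows <- lapply(seq_len(n), function(i) {
      extents <- c(
        sagittal = sag_extent[i],
        coronal = as.integer(round(spec$coronal_ratio * sag_extent[i])),
        transversal = as.integer(round(spec$transversal_ratio * sag_extent[i]))
      )
      profs <- lapply(ORIENTATIONS, function(o) {
        generate_profile(
          target_volume = vol[i], extent = extents[[o]],
          shape_power = spec$shape_power, shape_root = spec$shape_root,
          irregularity = spec$irregularity[[o]],
          orientation = o, subject_id = ids[i]
        )
      })
      tibble(
        subject_id = ids[i], sex = sex[i], true_volume_mm3 = vol[i],
        orientation = ORIENTATIONS, extent = unname(extents),
        profile = profs
      )
    })
    out <- bind_rows(rows)
    attr(out, "spec") <- spec
    out
  })
}

# truncated-normal draws by rejection; truncation at +/- 4 sd keeps the
# acceptance rate ~1, so the loop runs essentially once
rnorm_truncated <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(out < lower | out > upper)
  }
  out
}

#' True subject volumes of a cohort
#'
#' One row per subject with the ground-truth volume (the slice sum shared by
#' all three orientations), in roster order.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @return A tibble: `subject_id`, `sex` (if present), `true_volume_mm3`.
#' @export
cohort_volumes <- function(cohort) {
  keep <- intersect(c("subject_id", "sex", "true_volume_mm3"), names(cohort))
  distinct(cohort[keep])
}

#' Voxelize a sagittal area profile into a 3D mask
#'
#' Stacks elliptical cross-sections along the sagittal axis: slice `i` gets
#' an ellipse of area `area_mm2[i]` with a fixed semi-axis ratio, voxelized
#' at 1 mm. The default profile shape then voxelizes to an ellipsoid. Useful
#' as an end-to-end fixture: extracting the sagittal profile of the result
#' reproduces the input within voxelization error.
#'
#' @param profile A sagittal `icv_profile` on a 1 mm grid.
#' @param aspect_ratio Coronal-to-transversal semi-axis ratio of the
#'   cross-sections.
#' @return A `voxel_mask` with 1 mm voxels.
#' @export
profile_to_mask <- function(profile, aspect_ratio = 1.3) {
  check_profile(profile)
  if (abs(profile_voxel_size(profile) - 1) > 1e-8) {
    abort("`profile` must be on a 1 mm grid.")
  }
  areas <- profile$area_mm2
  if (any(areas > 0 & areas < 1)) {
    abort("areas below 1 mm^2 cannot be voxelized at 1 mm.")
  }
  # semi-axes: b (coronal) = aspect_ratio * c (transversal), pi*b*c = area
  c_ax <- sqrt(areas / (pi * aspect_ratio))
  b_ax <- aspect_ratio * c_ax
  ny <- 2L * ceiling(max(b_ax)) + 3L
  nz <- 2L * ceiling(max(c_ax)) + 3L
  y <- seq_len(ny) - (ny + 1) / 2
  z <- seq_len(nz) - (nz + 1) / 2
  data <- array(FALSE, dim = c(length(areas), ny, nz))
  yz2 <- outer(y^2, rep(1, nz)) # reused per slice with the z term added
  z2 <- outer(rep(1, ny), z^2)
  for (i in seq_along(areas)) {
    if (areas[i] <= 0) next
    data[i, , ] <- yz2 / b_ax[i]^2 + z2 / c_ax[i]^2 <= 1
  }
  voxel_mask(
    data,
    voxel_size = 1,
    axis_labels = c("sagittal", "coronal", "transversal"),
    subject_id = profile_subject(profile)
  )
}
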
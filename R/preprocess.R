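#' Intensity images and display conditioning
#'
#' Scalar MRI volumes are conditioned for manual segmentation in four steps:
#' a robust per-scan brightness measure, an additive brightness match to the
#' cohort grand mean, a tail-compressing contrast stretch, and a gamma
#' correction `y = B * (x/B)^gamma`. These steps shape what a human rater
#' sees; they do not enter the area/volume arithmetic, which works on binary
#' masks.
#'
#' `intensity_image()` wraps a 3D numeric array with its intensity ceiling
#' `B` (the representable tonal range is `[0, B-1]`, `B = 4096` for 12-bit
#' data) and per-axis voxel sizes in mm.
#'
#' @param data 3D numeric array with values in `[0, B-1]`.
#' @param B Intensity scale ceiling (`> 1`); 4096 for 12-bit scanners.
#' @param voxel_size Numeric length 1 or 3, mm per voxel edge along each axis.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(data, B = 4096, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    abort("`data` must be a 3D numeric array.")
  }
  if (length(B) != 1L || !is.finite(B) || B <= 1) abort("`B` must be > 1.")
  if (anyNA(data) || min(data) < 0 || max(data) > B - 1) {
    abort("all values must lie within [0, B-1].")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be 1 or 3 positive numbers.")
  }
  structure(
    list(data = data, B = as.numeric(B), voxel_size = voxel_size, log = character()),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "<intensity_image> %s grid, B = %g, voxels %s mm\n",
    paste(dim(x$data), collapse = "x"), x$B,
    paste(signif(x$voxel_size, 4), collapse = "x")
  ))
  if (length(x$log)) cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

log_step <- function(image, msg) {
  image$log <- c(image$log, msg)
  image
}

check_image <- function(image) {
  if (!inherits(image, "intensity_image")) {
    abort("expected an `intensity_image` (see intensity_image()).")
  }
  image
}

#' Robust mean intensity from the middle 80% of the tonal range
#'
#' The plain mean of a head scan mostly reflects how much background air the
#' field of view contains. Restricting the mean to voxels in the central 80%
#' of the representable range `[0.1*(B-1), 0.9*(B-1)]` removes background and
#' clipped highlights, so scans of small and large heads become comparable.
#'
#' @param image An `intensity_image`.
#' @return The mean intensity of in-band voxels.
#' @export
robust_mean <- function(image) {
  check_image(image)
  top <- image$B - 1
  inband <- image$data >= 0.1 * top & image$data <= 0.9 * top
  if (!any(inband)) {
    abort("degenerate image: no voxel within the central 80% of the tonal range.")
  }
  mean(image$data[inband])
}

#' Match a scan's robust brightness to a target
#'
#' Applies an additive intensity shift so that [robust_mean()] of the result
#' equals `target_mean`. Because shifting moves voxels in and out of the
#' central tonal band, the shift is iterated (at most `max_iter` times) until
#' the re-measured robust mean is within `tol` intensity units of the target.
#' Values are clipped to `[0, B-1]` after each shift.
#'
#' @param image An `intensity_image`.
#' @param target_mean Desired robust mean, strictly inside `(0, B-1)`.
#' @param tol Convergence tolerance in intensity units.
#' @param max_iter Iteration cap before giving up.
#' @return The shifted `intensity_image`.
#' @export
match_brightness <- function(image, target_mean, tol = 0.5, max_iter = 20L) {
  check_image(image)
  top <- image$B - 1
  if (!is.finite(target_mean) || target_mean <= 0 || target_mean >= top) {
    abort("`target_mean` must lie strictly inside (0, B-1).")
  }
  total_shift <- 0
  for (i in seq_len(max_iter)) {
    current <- robust_mean(image)
    delta <- target_mean - current
    if (abs(delta) <= tol) {
      return(log_step(image, sprintf(
        "match_brightness: shift %+.2f (converged in %d iteration%s)",
        total_shift, i - 1L, if (i == 2L) "" else "s"
      )))
    }
    image$data <- pmin(pmax(image$data + delta, 0), top)
    total_shift <- total_shift + delta
  }
  abort(sprintf(
    "brightness matching did not converge within %d iterations (residual %.2f).",
    max_iter, robust_mean(image) - target_mean
  ))
}

#' Tail-compressing contrast stretch
#'
#' Maps the darkest `tail_fraction` of voxels to 0 and the brightest
#' `tail_fraction` to `B-1`, rescaling the interior linearly onto the full
#' range. Compressing both tails expands the tonal range available to the
#' mid intensities, where the dura lives.
#'
#' @param image An `intensity_image`.
#' @param tail_fraction Fraction compressed at each end, in `(0, 0.5)`.
#' @return The stretched `intensity_image`.
#' @export
contrast_stretch <- function(image, tail_fraction = 0.10) {
  check_image(image)
  if (!is.finite(tail_fraction) || tail_fraction <= 0 || tail_fraction >= 0.5) {
    abort("`tail_fraction` must lie in (0, 0.5).")
  }
  qs <- quantile(image$data, c(tail_fraction, 1 - tail_fraction),
                 names = FALSE, type = 7)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) {
    abort("degenerate image: lower and upper stretch quantiles coincide.")
  }
  top <- image$B - 1
  image$data <- pmin(pmax((image$data - lo) / (hi - lo), 0), 1) * top
  log_step(image, sprintf(
    "contrast_stretch: tails %.0f%%, window [%.1f, %.1f] -> [0, %g]",
    100 * tail_fraction, lo, hi, top
  ))
}

#' Gamma correction
#'
#' Applies `y = B * (x / B)^gamma` voxel-wise. With `gamma < 1` mid-tones
#' brighten while the endpoints 0 and `B` are fixed; `gamma = 1` is the
#' identity. The map is strictly monotone for any `gamma > 0`.
#'
#' @param image An `intensity_image`.
#' @param gamma Exponent, `> 0`; 0.8 brightens as used for dura display.
#' @return The corrected `intensity_image`.
#' @export
gamma_correct <- function(image, gamma = 0.8) {
  check_image(image)
  if (!is.finite(gamma) || gamma <= 0) abort("`gamma` must be > 0.")
  if (min(image$data) < 0) abort("negative input values.")
  image$data <- image$B * (image$data / image$B)^gamma
  log_step(image, sprintf("gamma_correct: gamma = %g", gamma))
}

#' Condition one scan for display
#'
#' Convenience wrapper applying the conditioning chain in its canonical
#' order: brightness matching to `target_mean` (typically the cohort grand
#' mean of [robust_mean()] values), contrast stretch, then gamma correction.
#'
#' @inheritParams match_brightness
#' @inheritParams contrast_stretch
#' @inheritParams gamma_correct
#' @return The conditioned `intensity_image` with a step log attached.
#' @export
preprocess_image <- function(image, target_mean, tail_fraction = 0.10,
                             gamma = 0.8) {
  image %>%
    match_brightness(target_mean) %>%
    contrast_stretch(tail_fraction) %>%
    gamma_correct(gamma)
}

#' Resample onto an isotropic grid by linear interpolation
#'
#' Trilinear resampling implemented as three successive 1D linear
#' interpolations (the separable form of trilinear interpolation), with
#' voxel centers at `(i - 1) * voxel_size` along each axis. Masks are
#' resampled as scalars and re-binarised at 0.5.
#'
#' @param x An `intensity_image` or `voxel_mask`.
#' @param target_mm Target isotropic voxel edge in mm.
#' @param ... Unused.
#' @return An object of the same kind on a `target_mm` isotropic grid.
#' @export
resample_isotropic <- function(x, target_mm = 1.0, ...) {
  UseMethod("resample_isotropic")
}

#' @export
resample_isotropic.intensity_image <- function(x, target_mm = 1.0, ...) {
  if (!is.finite(target_mm) || target_mm <= 0) abort("`target_mm` must be > 0.")
  x$data <- resample_array(x$data, x$voxel_size, target_mm)
  x$voxel_size <- rep(target_mm, 3)
  log_step(x, sprintf("resample_isotropic: %g mm grid", target_mm))
}

#' @export
resample_isotropic.voxel_mask <- function(x, target_mm = 1.0, ...) {
  if (!is.finite(target_mm) || target_mm <= 0) abort("`target_mm` must be > 0.")
  values <- resample_array(
    array(as.numeric(x$data), dim = dim(x$data)),
    rep(x$voxel_size, 3), target_mm
  )
  voxel_mask(values > 0.5,
    voxel_size = target_mm,
    axis_labels = x$axis_labels, subject_id = x$subject_id
  )
}

# separable linear interpolation of a 3D array from per-axis spacings `from`
# (length 3) onto an isotropic spacing `to`; extent is preserved in mm
resample_array <- function(data, from, to) {
  for (axis in 1:3) {
    data <- interp_axis1(aperm(data, c(axis, setdiff(1:3, axis))),
                         from[axis], to)
    data <- aperm(data, order(c(axis, setdiff(1:3, axis))))
  }
  data
}

# linear interpolation along the first axis of a 3D array
interp_axis1 <- function(a, from, to) {
  n <- dim(a)[1]
  src <- (seq_len(n) - 1) * from
  tgt <- seq(0, src[n], by = to)
  if (n == 1L) {
    return(array(a, dim = c(length(tgt), dim(a)[2], dim(a)[3])))
  }
  lo <- pmin(findInterval(tgt, src), n - 1L)
  w <- (tgt - src[lo]) / from
  out <- a[lo, , , drop = FALSE] * (1 - w) + a[lo + 1L, , , drop = FALSE] * w
  array(out, dim = c(length(tgt), dim(a)[2], dim(a)[3]))
}
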
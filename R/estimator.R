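#' Enumerate the offset subsamples of a profile at one linear spacing
#'
#' Sampling every `spacing` mm admits exactly `spacing` distinct phase
#' positions: the first sampled slice must lie within one spacing of the
#' outermost positive-area slice on the designated starting side (anterior
#' for coronal, superior for transversal, the low-index end for sagittal —
#' profiles are stored in those directions). Offset `k` starts `k` slices in
#' from the support edge and steps by `spacing` until the support ends, so
#' the `spacing` subsamples partition the support slices.
#'
#' @param profile An [as_area_profile()] object on a 1 mm-compatible grid
#'   (`spacing` must be an integer multiple of the grid step).
#' @param spacing Linear spacing in mm, `>= 1` and at most the support length.
#' @return A tibble with one row per offset: columns `spacing_mm`, `offset`
#'   and a list-column `subsample` of `icv_subsample` objects.
#' @export
enumerate_subsamples <- function(profile, spacing) {
  check_profile(profile)
  vox <- profile_voxel_size(profile)
  step <- spacing / vox
  if (!is.finite(step) || abs(step - round(step)) > 1e-8 || step < 1) {
    abort("`spacing` must be a positive integer multiple of the grid step.")
  }
  step <- as.integer(round(step))
  idx <- which(profile$area_mm2 > 0)
  if (step > length(idx)) {
    abort(sprintf(
      "spacing %g mm exceeds the support length (%d slices of %g mm).",
      spacing, length(idx), vox
    ))
  }
  support <- profile_support(profile)
  subs <- lapply(seq_len(step) - 1L, function(k) {
    sel <- idx[seq.int(1L + k, length(idx), by = step)]
    structure(
      list(
        spacing = spacing,
        offset = k,
        positions = profile$position_mm[sel],
        areas = profile$area_mm2[sel],
        pad_positions = numeric(),
        support = support,
        voxel_size = vox,
        orientation = profile_orientation(profile),
        subject_id = profile_subject(profile)
      ),
      class = "icv_subsample"
    )
  })
  tibble(
    spacing_mm = spacing,
    offset = seq_len(step) - 1L,
    subsample = subs
  )
}

check_profile <- function(profile) {
  if (!inherits(profile, "icv_profile")) {
    abort("expected an `icv_profile` (see as_area_profile()).")
  }
  profile
}

#' @export
print.icv_subsample <- function(x, ...) {
  cat(sprintf(
    "<icv_subsample> %s/%s spacing %g offset %d: %d ICAs%s\n",
    x$subject_id, x$orientation, x$spacing, x$offset, length(x$areas),
    if (length(x$pad_positions)) " + 2 zero pads" else ""
  ))
  invisible(x)
}

#' Append zero areas where the vault ends
#'
#' The piecewise linear and cubic spline interpolants need anchors at the
#' borders of the intracranial vault, otherwise they cannot reach the
#' positions where the area drops to zero. A zero-area point is appended one
#' voxel beyond the outermost positive-area slice on each side — the first
#' empty slice. The piecewise constant estimator does not use pads.
#'
#' @param sub An `icv_subsample` from [enumerate_subsamples()].
#' @param profile The source profile (defines where the support ends).
#' @return The subsample with its two `pad_positions` filled in.
#' @export
pad_zeros <- function(sub, profile = NULL) {
  check_subsample(sub)
  support <- if (is.null(profile)) sub$support else {
    check_profile(profile)
    profile_support(profile)
  }
  vox <- sub$voxel_size
  sub$pad_positions <- c(support[1] - vox, support[2] + vox)
  sub
}

check_subsample <- function(sub) {
  if (!inherits(sub, "icv_subsample")) {
    abort("expected an `icv_subsample` (see enumerate_subsamples()).")
  }
  sub
}

# padded (position, area) points, sorted
padded_points <- function(sub) {
  if (length(sub$pad_positions) != 2L) {
    abort("subsample has no zero pads; apply pad_zeros() first.")
  }
  x <- c(sub$pad_positions[1], sub$positions, sub$pad_positions[2])
  list(x = x, y = c(0, sub$areas, 0))
}

estimate_record <- function(sub, value, method) {
  tibble(
    subject_id = sub$subject_id,
    orientation = sub$orientation,
    method = method,
    spacing_mm = sub$spacing,
    offset = sub$offset,
    value_mm3 = value
  )
}

#' Volume estimates from one subsample
#'
#' Three interpolation schemes turn a subsample of linearly spaced areas
#' into a volume estimate:
#'
#' * `estimate_constant()`: piecewise constant — each sampled area stands in
#'   for a slab of thickness `spacing`, so the estimate is
#'   `sum(areas) * spacing`. Zero pads are ignored (a zero area contributes
#'   nothing to the sum).
#' * `estimate_linear()`: piecewise linear — the trapezoidal integral through
#'   the sampled areas and the two zero pads, with the actual (possibly
#'   shorter) end spacings next to the pads.
#' * `estimate_spline()`: the exact analytic integral of the not-a-knot cubic
#'   spline through the padded points, from pad to pad. The spline is not
#'   clamped at zero: negative lobes near the pads integrate as-is (a
#'   warning of class `icvsparse_negative_spline` is raised when any segment
#'   dips below zero, and the estimate is additionally flagged if it is
#'   itself non-positive).
#'
#' @param sub An `icv_subsample`; for `estimate_linear()`/`estimate_spline()`
#'   it must carry zero pads (see [pad_zeros()]).
#' @param warn_negative Raise the negative-lobe warning? (Spline only.)
#' @return A one-row tibble: `subject_id`, `orientation`, `method`,
#'   `spacing_mm`, `offset`, `value_mm3`.
#' @export
estimate_constant <- function(sub) {
  check_subsample(sub)
  estimate_record(sub, sum(sub$areas) * sub$spacing, "constant")
}

#' @rdname estimate_constant
#' @export
estimate_linear <- function(sub) {
  check_subsample(sub)
  pts <- padded_points(sub)
  if (length(pts$x) < 2L) abort("need at least 2 points.")
  value <- sum(diff(pts$x) * (head(pts$y, -1) + tail(pts$y, -1)) / 2)
  estimate_record(sub, value, "linear")
}

#' @rdname estimate_constant
#' @export
estimate_spline <- function(sub, warn_negative = TRUE) {
  check_subsample(sub)
  pts <- padded_points(sub)
  if (length(pts$x) < 2L) abort("need at least 2 points.")
  sp <- notaknot_spline(pts$x, pts$y)
  value <- spline_integral(sp)
  if (warn_negative && spline_min(sp) < 0) {
    warn(
      sprintf(
        "spline dips below zero for subject %s (%s, spacing %g, offset %d)%s",
        sub$subject_id, sub$orientation, sub$spacing, sub$offset,
        if (value <= 0) "; the estimate itself is non-positive" else ""
      ),
      class = "icvsparse_negative_spline"
    )
  }
  estimate_record(sub, value, "spline")
}

#' Estimate intracranial volume from sparse slice areas
#'
#' The front door of the estimator: selects the requested offset
#' subsample(s) at one linear spacing, applies zero pads where the method
#' needs them, and dispatches to the interpolation scheme(s). With
#' `offset = NULL` all `spacing` offsets are returned, which is the input
#' to every validity computation.
#'
#' @inheritParams enumerate_subsamples
#' @param offset Offset(s) in `0:(spacing-1)`, or `NULL` for all.
#' @param method One or more of `"constant"`, `"linear"`, `"spline"`.
#' @param warn_negative Passed to [estimate_spline()].
#' @return A tibble with one row per offset and method (columns as in
#'   [estimate_constant()]).
#' @examples
#' p <- generate_profile(1.5e6, extent = 136, seed = 1)
#' estimate_icv(p, spacing = 10, offset = 0, method = "spline")
#' @export
estimate_icv <- function(profile, spacing, offset = NULL,
                         method = c("constant", "linear", "spline"),
                         warn_negative = TRUE) {
  method <- match.arg(method, several.ok = TRUE)
  subs <- enumerate_subsamples(profile, spacing)
  if (!is.null(offset)) {
    if (!all(offset %in% subs$offset)) {
      abort(sprintf("`offset` must lie in 0:%d.", max(subs$offset)))
    }
    subs <- subs[subs$offset %in% offset, ]
  }
  rows <- lapply(subs$subsample, function(sub) {
    padded <- pad_zeros(sub)
    bind_rows(lapply(method, function(m) {
      switch(m,
        constant = estimate_constant(sub),
        linear = estimate_linear(padded),
        spline = estimate_spline(padded, warn_negative = warn_negative)
      )
    }))
  })
  bind_rows(rows)
}
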
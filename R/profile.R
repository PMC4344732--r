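#' Area profiles: ordered cross-sectional areas along one anatomical axis
#'
#' An area profile holds the intracranial area (ICA, mm^2) of every slice of
#' one subject along one slicing orientation, at the slice centers
#' `position_mm = slice index * voxel_size`. It is the object all volume
#' estimators consume. Profiles are tibbles with columns `position_mm` and
#' `area_mm2` plus attributes `orientation`, `subject_id` and `voxel_size`.
#'
#' Construction enforces the geometry the estimators rely on: positions
#' strictly increasing on a constant grid equal to `voxel_size`, nonnegative
#' areas with at least one positive, and contiguous support — the slices with
#' positive area form a single run. Isolated islands of voxels would create
#' interior zero-area gaps; real intracranial vaults are contiguous, so such
#' profiles are rejected rather than silently integrated.
#'
#' @param x A data frame with numeric columns `position_mm` and `area_mm2`.
#' @param orientation One of `"sagittal"`, `"coronal"`, `"transversal"`.
#' @param subject_id Opaque subject identifier (character scalar).
#' @param voxel_size Grid step in mm; inferred from the positions when `NULL`.
#'
#' @return A tibble of class `icv_profile`.
#' @examples
#' df <- data.frame(position_mm = 0:4, area_mm2 = c(0, 10, 25, 10, 0))
#' p <- as_area_profile(df, orientation = "sagittal", subject_id = "s1")
#' profile_volume(p)
#' @export
as_area_profile <- function(x, orientation, subject_id = "subject",
                            voxel_size = NULL) {
  if (!is.data.frame(x) || !all(c("position_mm", "area_mm2") %in% names(x))) {
    abort("`x` must be a data frame with columns `position_mm` and `area_mm2`.")
  }
  new_area_profile(
    positions = as.numeric(x$position_mm),
    areas = as.numeric(x$area_mm2),
    orientation = orientation,
    subject_id = subject_id,
    voxel_size = voxel_size
  )
}

new_area_profile <- function(positions, areas, orientation,
                             subject_id = "subject", voxel_size = NULL) {
  check_orientation(orientation)
  if (length(positions) != length(areas) || length(positions) < 1L) {
    abort("`positions` and `areas` must have equal, positive length.")
  }
  steps <- diff(positions)
  if (length(steps) > 0L) {
    if (any(steps <= 0)) abort("`positions` must be strictly increasing.")
    if (diff(range(steps)) > 1e-8 * max(steps)) {
      abort("`positions` must lie on a constant grid.")
    }
  }
  if (is.null(voxel_size)) {
    voxel_size <- if (length(steps) > 0L) steps[1] else 1
  }
  if (voxel_size <= 0) abort("`voxel_size` must be > 0.")
  if (length(steps) > 0L && abs(steps[1] - voxel_size) > 1e-8 * voxel_size) {
    abort("position step must equal `voxel_size`.")
  }
  if (any(areas < 0)) abort("areas must be nonnegative.")
  support <- which(areas > 0)
  if (length(support) == 0L) abort("at least one area must be positive.")
  if (!all(diff(support) == 1L)) {
    abort(paste0(
      "non-contiguous support: slices with positive area must form a single ",
      "run (interior zero-area gaps found at slice index ",
      support[which(diff(support) != 1L)[1]] + 1L, ")."
    ))
  }
  out <- new_tibble(
    list(position_mm = as.numeric(positions), area_mm2 = as.numeric(areas)),
    nrow = length(positions),
    class = "icv_profile"
  )
  attr(out, "orientation") <- orientation
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "voxel_size") <- as.numeric(voxel_size)
  out
}

#' @export
print.icv_profile <- function(x, ...) {
  cat(sprintf(
    "<icv_profile> %s, subject %s, %d slices @ %g mm, volume %.0f mm^3\n",
    profile_orientation(x), profile_subject(x), nrow(x),
    profile_voxel_size(x), profile_volume(x)
  ))
  NextMethod()
}

#' Profile accessors
#'
#' Small helpers reading the metadata carried by an [as_area_profile()]
#' object: its orientation, subject id, grid step, slice-sum volume and the
#' positions bounding its positive-area support.
#'
#' @param profile An `icv_profile`.
#' @return `profile_volume()` returns the slice-sum volume
#'   `sum(area_mm2) * voxel_size` in mm^3; `profile_support()` a length-2
#'   numeric vector (first and last positive-area position in mm); the others
#'   scalars.
#' @export
profile_volume <- function(profile) {
  sum(profile$area_mm2) * profile_voxel_size(profile)
}

#' @rdname profile_volume
#' @export
profile_support <- function(profile) {
  idx <- which(profile$area_mm2 > 0)
  c(profile$position_mm[idx[1]], profile$position_mm[idx[length(idx)]])
}

#' @rdname profile_volume
#' @export
profile_orientation <- function(profile) attr(profile, "orientation")

#' @rdname profile_volume
#' @export
profile_subject <- function(profile) attr(profile, "subject_id")

#' @rdname profile_volume
#' @export
profile_voxel_size <- function(profile) attr(profile, "voxel_size")

#' Read and write area profiles as CSV with a JSON sidecar
#'
#' Profiles are stored as plain CSV with header `position_mm,area_mm2`; the
#' orientation, subject id and grid step travel in a JSON sidecar named
#' `<path>.json` so the CSV stays trivially loadable by any tool.
#'
#' @param profile An `icv_profile`.
#' @param path CSV path; the sidecar is written/read at `paste0(path, ".json")`.
#' @return `write_profile()` returns `path` invisibly; `read_profile()` the
#'   reconstructed `icv_profile`.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(as_tibble(profile)[c("position_mm", "area_mm2")], path)
  meta <- list(
    orientation = profile_orientation(profile),
    subject_id = profile_subject(profile),
    voxel_size = profile_voxel_size(profile)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("metadata sidecar not found: ", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  as_area_profile(df,
    orientation = meta$orientation,
    subject_id = meta$subject_id,
    voxel_size = meta$voxel_size
  )
}
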
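#' Voxel masks: 3D binary intracranial segmentations
#'
#' A `voxel_mask` wraps a 3D logical array on an isotropic grid together with
#' the mapping of its array axes to the three anatomical slicing orientations.
#' It is the ground-truth object: its voxel count times the voxel volume is
#' the reference intracranial volume every estimate is compared against.
#'
#' @param data 3D array, logical or coercible to logical; at least one voxel
#'   must be `TRUE`.
#' @param voxel_size Edge length of the (isotropic) voxels in mm.
#' @param axis_labels Character vector of length 3 assigning each array axis
#'   an orientation; must be a permutation of `"sagittal"`, `"coronal"`,
#'   `"transversal"`.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `voxel_mask`.
#' @examples
#' m <- voxel_mask(array(TRUE, c(10, 10, 10)))
#' total_volume(m)
#' area_profile(m, "coronal")
#' @export
voxel_mask <- function(data, voxel_size = 1,
                       axis_labels = c("sagittal", "coronal", "transversal"),
                       subject_id = "subject") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) abort("`data` must not contain NA.")
  if (!any(data)) abort("mask must contain at least one TRUE voxel.")
  if (length(voxel_size) != 1L || !is.finite(voxel_size) || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (isotropic grid).")
  }
  if (length(axis_labels) != 3L || !setequal(axis_labels, ORIENTATIONS)) {
    abort("`axis_labels` must be a permutation of sagittal, coronal, transversal.")
  }
  structure(
    list(
      data = data,
      voxel_size = as.numeric(voxel_size),
      axis_labels = as.character(axis_labels),
      subject_id = as.character(subject_id)
    ),
    class = "voxel_mask"
  )
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf(
    "<voxel_mask> subject %s, %s grid @ %g mm (%s), %d voxels, %.0f mm^3\n",
    x$subject_id, paste(dim(x$data), collapse = "x"), x$voxel_size,
    paste(substr(x$axis_labels, 1, 3), collapse = "/"),
    sum(x$data), total_volume(x)
  ))
  invisible(x)
}

#' Exact reference volume of a segmentation
#'
#' For a mask this is the number of `TRUE` voxels times the voxel volume; for
#' an area profile the slice-sum `sum(area) * voxel_size`. The two agree
#' exactly when the profile was extracted from the mask, which makes the
#' slice-sum identity a useful integrity check.
#'
#' @param x A `voxel_mask` or `icv_profile`.
#' @param ... Unused.
#' @return Volume in mm^3.
#' @export
total_volume <- function(x, ...) UseMethod("total_volume")

#' @export
total_volume.voxel_mask <- function(x, ...) sum(x$data) * x$voxel_size^3

#' @export
total_volume.icv_profile <- function(x, ...) profile_volume(x)

#' Extract the slice-wise area profile of a mask
#'
#' Counts `TRUE` voxels in every slice perpendicular to the requested
#' orientation and scales by `voxel_size^2`, yielding the intracranial area
#' (ICA) sequence of that orientation. Slice `i` (0-based) sits at position
#' `i * voxel_size`. This is how coronal and transversal ICA sequences are
#' reconstructed from a sagittally segmented volume.
#'
#' @param mask A `voxel_mask`.
#' @param orientation `"sagittal"`, `"coronal"` or `"transversal"`.
#' @return An `icv_profile` whose length equals the grid extent on that axis.
#' @export
area_profile <- function(mask, orientation) {
  if (!inherits(mask, "voxel_mask")) abort("`mask` must be a voxel_mask.")
  check_orientation(orientation)
  axis <- match(orientation, mask$axis_labels)
  counts <- apply(mask$data, axis, sum)
  new_area_profile(
    positions = (seq_along(counts) - 1) * mask$voxel_size,
    areas = counts * mask$voxel_size^2,
    orientation = orientation,
    subject_id = mask$subject_id,
    voxel_size = mask$voxel_size
  )
}

#' Read and write binary masks as NIfTI
#'
#' `read_mask()` loads a NIfTI volume, checks that the voxels are isotropic
#' (anisotropic data must go through [resample_isotropic()] first), derives
#' the axis-to-orientation mapping from the image's orientation code (an
#' R/L axis is sagittal, A/P coronal, S/I transversal) and binarises at 0.5.
#' `write_mask()` stores the mask as an 8-bit NIfTI with the matching pixdim.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param subject_id Subject identifier to attach; defaults to the file stem.
#' @param mask A `voxel_mask`.
#' @return `read_mask()` a `voxel_mask`; `write_mask()` `path`, invisibly.
#' @export
read_mask <- function(path, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  pix <- pix[seq_len(3)]
  if (diff(range(pix)) > 1e-4 * max(pix)) {
    abort(paste0(
      "anisotropic voxels (", paste(signif(pix, 4), collapse = " x "),
      " mm): resample to an isotropic grid first (see resample_isotropic())."
    ))
  }
  code <- RNifti::orientation(img)
  labels <- vapply(strsplit(code, "")[[1]], function(ch) {
    switch(ch,
      R = "sagittal", L = "sagittal",
      A = "coronal", P = "coronal",
      S = "transversal", I = "transversal",
      abort(paste0("unrecognised orientation code: ", code))
    )
  }, character(1))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  voxel_mask(
    data = array(as.array(img) > 0.5, dim = dim(img)),
    voxel_size = pix[1],
    axis_labels = unname(labels),
    subject_id = subject_id
  )
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "voxel_mask")) abort("`mask` must be a voxel_mask.")
  img <- RNifti::asNifti(
    array(as.integer(mask$data), dim = dim(mask$data)),
    reference = list(pixdim = c(-1, rep(mask$voxel_size, 3), 0, 0, 0, 0)),
    datatype = "uint8"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}
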
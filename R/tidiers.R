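#' Tidy a validity evaluation
#'
#' `tidy()` returns the long percentile table (one row per spacing,
#' orientation, method, metric and percentile); `glance()` a one-row
#' summary of the evaluation design.
#'
#' @param x An `icv_validity` from [evaluate_validity()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.icv_validity <- function(x, ...) x$percentiles

#' @rdname tidy.icv_validity
#' @export
glance.icv_validity <- function(x, ...) {
  cfg <- x$config
  tibble(
    n_subjects = cfg$n_subjects,
    n_settings = length(cfg$spacings) * length(cfg$orientations) *
      length(cfg$methods),
    n_spacings = length(cfg$spacings),
    n_orientations = length(cfg$orientations),
    n_methods = length(cfg$methods),
    combinations = cfg$count,
    seed = cfg$seed
  )
}

#' Write a validity evaluation to disk
#'
#' Writes the long percentile CSV, the paired-test CSV and a JSON run
#' manifest (seed, design, package version) into `dir`.
#'
#' @param x An `icv_validity`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_validity <- function(x, dir) {
  if (!inherits(x, "icv_validity")) abort("`x` must be an icv_validity.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$percentiles, file.path(dir, "percentiles.csv"))
  if (nrow(x$paired)) {
    readr::write_csv(x$paired, file.path(dir, "paired_tests.csv"))
  }
  manifest <- c(x$config, list(
    package = "icvsparse",
    version = as.character(utils::packageVersion("icvsparse"))
  ))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
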
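#' Two-way ANOVA decomposition behind the absolute-agreement ICC
#'
#' Decomposes an `n x 2` table — true volume and estimate per subject — into
#' the mean squares of a two-way ANOVA with subjects as targets and the two
#' measurements as raters: between-target (`ms_rows`), between-rater
#' (`ms_cols`, which captures systematic bias) and residual (`ms_err`).
#'
#' @param x Numeric vector of true volumes (one per subject).
#' @param y Numeric vector of estimates, same length.
#' @return A one-row tibble: `ms_rows`, `ms_cols`, `ms_err`, `n_targets`,
#'   `k_raters`.
#' @export
anova_decomposition <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("`x` and `y` must have equal length >= 2.")
  }
  n <- length(x)
  grand <- mean(c(x, y))
  rows <- (x + y) / 2
  ss_rows <- 2 * sum((rows - grand)^2)
  ss_cols <- n * ((mean(x) - grand)^2 + (mean(y) - grand)^2)
  resid <- (x - rows - mean(x) + grand)^2 + (y - rows - mean(y) + grand)^2
  tibble(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / 1,
    ms_err = sum(resid) / (n - 1),
    n_targets = n,
    k_raters = 2L
  )
}

#' Single-measure absolute-agreement intraclass correlation, ICC(A,1)
#'
#' The intraclass correlation from a two-way ANOVA for single measurements
#' and absolute agreement:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2` raters
#' (truth and estimate) and `n` subjects. Unlike Pearson correlation it
#' penalizes systematic bias through the between-rater mean square. For
#' single-measure absolute agreement the two-way random and two-way mixed
#' models give the same point estimate; both flags are accepted.
#'
#' @inheritParams anova_decomposition
#' @param model `"random"` or `"mixed"`; the point estimate is identical.
#' @return The ICC as a single number in `[-1, 1]`.
#' @examples
#' x <- c(1.41, 1.52, 1.66, 1.38, 1.59) * 1e6
#' icc_single_absolute(x, x + 5e4) # bias pulls the ICC below 1
#' @export
icc_single_absolute <- function(x, y, model = c("random", "mixed")) {
  match.arg(model)
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  val <- icc_columns(x, matrix(y, ncol = 1))
  if (!is.finite(val)) {
    abort("degenerate input: no variance anywhere in the two-way table.")
  }
  val
}

# vectorized ICC(A,1) of x against each column of Y (k = 2 raters)
icc_columns <- function(x, Y) {
  n <- length(x)
  xbar <- mean(x)
  ybar <- colMeans(Y)
  d <- x - Y                      # per-subject differences, recycled by column
  dbar <- xbar - ybar
  ms_err <- (colSums(d^2) - n * dbar^2) / (2 * (n - 1))
  rows2 <- (x + Y) / 2
  grand <- (xbar + ybar) / 2
  ms_rows <- 2 * (colSums(rows2^2) - n * grand^2 -
                  2 * grand * (colSums(rows2) - n * grand)) / (n - 1)
  ms_cols <- n * dbar^2 / 2
  num <- ms_rows - ms_err
  den <- ms_rows + ms_err + (2 / n) * (ms_cols - ms_err)
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

#' Generalized Jaccard index of paired volumes
#'
#' `sum(pmin(x, y)) / sum(pmax(x, y))` over paired positive volumes — the
#' generalized (Ruzicka) Jaccard index, 1 iff the vectors agree exactly.
#'
#' @param x,y Equal-length vectors of positive volumes (mm^3).
#' @return A number in `(0, 1]`.
#' @export
jaccard_volumes <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    abort("`x` and `y` must have equal, positive length.")
  }
  if (any(x <= 0) || any(y <= 0)) abort("all volumes must be positive.")
  sum(pmin(x, y)) / sum(pmax(x, y))
}

#' Signed percentage error of an estimate
#'
#' `100 * (estimate - truth) / truth`; positive for overestimates.
#' Vectorized over both arguments.
#'
#' @param estimate Estimated volume(s), mm^3.
#' @param truth True volume(s), `> 0`.
#' @return Percentage error(s), signed.
#' @export
percentage_error <- function(estimate, truth) {
  if (any(truth <= 0)) abort("`truth` must be positive.")
  100 * (estimate - truth) / truth
}

#' Random offset combinations for the validity Monte-Carlo
#'
#' One combination assigns each subject one of its `spacing` offsets,
#' independently and uniformly; the estimate space of a cohort of `m`
#' subjects holds `spacing^m` such combinations, so they are sampled with
#' replacement rather than enumerated. A fixed `seed` makes the draw
#' reproducible, and the same matrix is reused for every interpolation
#' method of one (spacing, orientation) setting.
#'
#' @param n_subjects Number of subjects.
#' @param spacing Linear spacing in mm (offsets are `0:(spacing-1)`).
#' @param count Number of combinations to draw.
#' @param seed Optional integer seed (the draw runs in an isolated RNG
#'   stream and leaves the global RNG untouched).
#' @return An integer matrix, `n_subjects` rows by `count` columns, with
#'   the seed stored in `attr(, "seed")`.
#' @export
sample_combinations <- function(n_subjects, spacing, count = 2000,
                                seed = NULL) {
  if (n_subjects < 1L || spacing < 1L || count < 1L) {
    abort("`n_subjects`, `spacing` and `count` must all be >= 1.")
  }
  draw <- function() {
    matrix(
      sample.int(spacing, n_subjects * count, replace = TRUE) - 1L,
      nrow = n_subjects, ncol = count
    )
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "seed") <- seed
  out
}

# deterministic per-(spacing, orientation) substream seed so each setting is
# reproducible on its own, whatever grid it is requested in
substream_seed <- function(master, spacing, orientation) {
  oidx <- match(orientation, ORIENTATIONS)
  as.integer((as.numeric(master) %% 2147483647 +
                7919 * (3 * spacing + oidx)) %% 2147483647)
}

#' Paired comparison of piecewise constant and cubic spline errors
#'
#' For each subject the mean absolute percentage error (MAPE) over all
#' `spacing` offsets is computed for the piecewise constant and cubic
#' spline estimators; the per-subject MAPE pairs are then compared with a
#' paired Student's t-test. A positive mean difference (constant minus
#' spline) means the spline improves on the constant interpolation.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]): columns
#'   `subject_id`, `orientation` and list-column `profile`.
#' @param spacing One or more linear spacings in mm.
#' @param orientation Which profiles to use.
#' @return A tibble with one row per spacing: `orientation`, `spacing_mm`,
#'   `n_subjects`, `mean_mape_constant`, `mean_mape_spline`, `mean_diff`,
#'   `conf_low`, `conf_high`, `statistic`, `p_value`.
#' @export
compare_interpolators <- function(cohort, spacing, orientation = "sagittal") {
  check_orientation(orientation)
  profiles <- cohort_profiles(cohort, orientation)
  if (length(profiles) < 3L) abort("need a cohort of at least 3 subjects.")
  truth <- vapply(profiles, profile_volume, numeric(1))
  map_dfr(spacing, function(s) {
    E <- estimate_matrices(profiles, s, c("constant", "spline"))
    mape_c <- rowMeans(abs(percentage_error(E$constant, truth)))
    mape_s <- rowMeans(abs(percentage_error(E$spline, truth)))
    paired_record(mape_c, mape_s) %>%
      mutate(orientation = orientation, spacing_mm = s, .before = 1)
  })
}

paired_record <- function(mape_constant, mape_spline) {
  d <- mape_constant - mape_spline
  if (sd(d) == 0) {
    # degenerate paired t (zero variance of differences); report t = 0 when
    # the means agree exactly rather than erroring out
    return(tibble(
      n_subjects = length(d),
      mean_mape_constant = mean(mape_constant),
      mean_mape_spline = mean(mape_spline),
      mean_diff = mean(d),
      conf_low = mean(d), conf_high = mean(d),
      statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
      p_value = if (mean(d) == 0) 1 else 0
    ))
  }
  tt <- t.test(mape_constant, mape_spline, paired = TRUE)
  tibble(
    n_subjects = length(d),
    mean_mape_constant = mean(mape_constant),
    mean_mape_spline = mean(mape_spline),
    mean_diff = unname(tt$estimate),
    conf_low = tt$conf.int[1],
    conf_high = tt$conf.int[2],
    statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}

# profiles of one orientation in roster (first-appearance) order
cohort_profiles <- function(cohort, orientation) {
  if (!is.data.frame(cohort) ||
      !all(c("subject_id", "orientation", "profile") %in% names(cohort))) {
    abort("`cohort` must have columns subject_id, orientation, profile.")
  }
  roster <- unique(cohort$subject_id)
  sub <- cohort[cohort$orientation == orientation, ]
  if (!setequal(sub$subject_id, roster)) {
    abort(sprintf("every subject needs a %s profile.", orientation))
  }
  sub <- sub[match(roster, sub$subject_id), ]
  stats::setNames(sub$profile, sub$subject_id)
}

# n_subjects x n_offsets estimate matrix per method (offsets in column order)
estimate_matrices <- function(profiles, spacing, methods) {
  per_subject <- lapply(profiles, function(p) {
    est <- estimate_icv(p, spacing, method = methods, warn_negative = FALSE)
    n_off <- nrow(est) / length(methods)
    a <- vapply(methods, function(m) est$value_mm3[est$method == m],
                numeric(n_off))
    matrix(a, nrow = n_off, dimnames = list(NULL, methods))
  })
  n_off <- nrow(per_subject[[1]])
  out <- lapply(seq_along(methods), function(j) {
    v <- vapply(per_subject, function(a) a[, j], numeric(n_off))
    t(matrix(v, nrow = n_off)) # n_subjects x n_offsets, also when n_off == 1
  })
  stats::setNames(out, methods)
}

#' Monte-Carlo validity evaluation across spacings, orientations and methods
#'
#' The full validity procedure: for every (spacing, orientation) setting all
#' `spacing` offset estimates of every subject are precomputed for each
#' interpolation method, `count` random offset combinations are drawn once
#' and shared across the methods, and each combination's estimates are
#' compared with the true volumes via ICC(A,1), Pearson correlation and the
#' generalized Jaccard index; signed percentage errors are pooled over all
#' member estimates of all combinations. Percentile curves (by default the
#' 5th, 25th, 50th, 75th and 95th) summarise each metric's distribution, and
#' piecewise constant vs cubic spline MAPEs are compared per subject with a
#' paired t-test whenever both methods are evaluated.
#'
#' Degenerate metric values (for example an ICC whose denominator vanishes)
#' are recorded as missing with a warning, never silently dropped.
#'
#' @inheritParams compare_interpolators
#' @param spacings Integer linear spacings in mm (the full study grid is
#'   `2:50`).
#' @param orientations Subset of `"sagittal"`, `"coronal"`, `"transversal"`.
#' @param methods Subset of `"constant"`, `"linear"`, `"spline"`.
#' @param count Combinations per setting.
#' @param seed Master seed; each (spacing, orientation) setting derives its
#'   own reproducible substream from it.
#' @param percentile_levels Percentile levels of the summary curves.
#' @return An object of class `icv_validity`; see [tidy.icv_validity()].
#' @examples
#' cohort <- generate_cohort(population_spec(n_female = 4, n_male = 3, seed = 1))
#' ev <- evaluate_validity(cohort, spacings = c(5, 10), count = 200, seed = 1)
#' tidy(ev)
#' @export
evaluate_validity <- function(cohort,
                              spacings = 2:50,
                              orientations = c("sagittal", "coronal", "transversal"),
                              methods = c("constant", "linear", "spline"),
                              count = 2000,
                              seed = 1L,
                              percentile_levels = c(5, 25, 50, 75, 95)) {
  orientations <- match.arg(orientations, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(spacings < 1) || any(spacings != round(spacings))) {
    abort("`spacings` must be positive integers (mm).")
  }

  percentile_rows <- list()
  summary_rows <- list()
  paired_rows <- list()
  n_negative <- 0L

  for (o in orientations) {
    profiles <- cohort_profiles(cohort, o)
    truth <- vapply(profiles, profile_volume, numeric(1))
    n_subj <- length(profiles)
    for (s in spacings) {
      E <- estimate_matrices(profiles, s, methods)
      if (ncol(E[[1]]) != s) {
        abort("offset count differs from spacing: profiles must be on a 1 mm grid.")
      }
      combos <- sample_combinations(n_subj, s, count,
                                    seed = substream_seed(seed, s, o))
      lin <- as.vector(seq_len(n_subj) + combos * n_subj)
      for (m in methods) {
        Y <- matrix(E[[m]][lin], nrow = n_subj, ncol = count)
        pe <- percentage_error(Y, truth)
        metrics <- list(
          icc = icc_columns(truth, Y),
          pearson = as.vector(cor(truth, Y)),
          jaccard = colSums(pmin(Y, truth)) / colSums(pmax(Y, truth)),
          pct_error = as.vector(pe),
          abs_pct_error = abs(as.vector(pe))
        )
        for (metric in names(metrics)) {
          v <- metrics[[metric]]
          if (anyNA(v) || any(!is.finite(v))) {
            warn(sprintf(
              "degenerate %s values at spacing %d (%s, %s) recorded as missing",
              metric, s, o, m
            ))
            v[!is.finite(v)] <- NA_real_
          }
          qs <- quantile(v, percentile_levels / 100, na.rm = TRUE,
                         names = FALSE, type = 7)
          percentile_rows[[length(percentile_rows) + 1L]] <- tibble(
            spacing_mm = s, orientation = o, method = m, metric = metric,
            percentile = percentile_levels, value = qs
          )
          summary_rows[[length(summary_rows) + 1L]] <- tibble(
            spacing_mm = s, orientation = o, method = m, metric = metric,
            mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
            n = length(v), n_missing = sum(is.na(v))
          )
        }
      }
      if (all(c("constant", "spline") %in% methods)) {
        mape_c <- rowMeans(abs(percentage_error(E$constant, truth)))
        mape_s <- rowMeans(abs(percentage_error(E$spline, truth)))
        paired_rows[[length(paired_rows) + 1L]] <-
          paired_record(mape_c, mape_s) %>%
          mutate(orientation = o, spacing_mm = s, .before = 1)
      }
    }
  }

  structure(
    list(
      percentiles = bind_rows(percentile_rows),
      summary = bind_rows(summary_rows),
      paired = bind_rows(paired_rows),
      config = list(
        spacings = spacings, orientations = orientations, methods = methods,
        count = count, seed = seed, percentile_levels = percentile_levels,
        n_subjects = length(unique(cohort$subject_id))
      )
    ),
    class = "icv_validity"
  )
}

#' @export
print.icv_validity <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    paste0(
      "<icv_validity> %d subjects, %d settings ",
      "(%d spacings x %d orientations x %d methods), %d combinations each\n"
    ),
    cfg$n_subjects,
    length(cfg$spacings) * length(cfg$orientations) * length(cfg$methods),
    length(cfg$spacings), length(cfg$orientations), length(cfg$methods),
    cfg$count
  ))
  cat("  percentile curves in $percentiles / tidy(); paired tests in $paired\n")
  invisible(x)
}
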
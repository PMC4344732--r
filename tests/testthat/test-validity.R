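test_that("ICC(A,1) matches an independent two-way ANOVA computation", {
  x <- c(1.41, 1.52, 1.66, 1.38, 1.59, 1.47, 1.71, 1.55) * 1e6
  expect_equal(icc_single_absolute(x, x), 1)
  # absolute agreement penalizes bias that Pearson ignores
  biased <- icc_single_absolute(x, x + 2e5)
  expect_lt(biased, 1)
  expect_equal(cor(x, x + 2e5), 1)
  expect_equal(icc_single_absolute(x, x + 2e5, model = "mixed"), biased)
  # oracle: mean squares from stats::aov on the long-format two-way layout
  set.seed(15)
  for (rep in 1:5) {
    y <- x * runif(8, 0.9, 1.1) + rnorm(8, sd = 5e4)
    long <- data.frame(
      value = c(x, y),
      subject = factor(rep(seq_along(x), 2)),
      rater = factor(rep(1:2, each = length(x)))
    )
    ms <- summary(stats::aov(value ~ subject + rater, data = long))[[1]][
      , "Mean Sq"]
    k <- 2; n <- length(x)
    oracle <- (ms[1] - ms[3]) /
      (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
    expect_equal(icc_single_absolute(x, y), oracle, tolerance = 1e-12)
    dec <- anova_decomposition(x, y)
    expect_equal(dec$ms_rows, ms[1], tolerance = 1e-12)
    expect_equal(dec$ms_cols, ms[2], tolerance = 1e-12)
    expect_equal(dec$ms_err, ms[3], tolerance = 1e-12)
  }
  expect_error(icc_single_absolute(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(icc_single_absolute(x[1:2], x[1:2]), "length")
})

test_that("the Jaccard index follows sum-min over sum-max", {
  expect_equal(jaccard_volumes(1, 2), 0.5)
  expect_equal(jaccard_volumes(c(100, 200), c(110, 190)), 290 / 310)
  x <- c(3, 5, 9); y <- c(4, 2, 9.5)
  expect_equal(jaccard_volumes(x, x), 1)
  expect_equal(jaccard_volumes(x, y), jaccard_volumes(y, x))
  expect_equal(jaccard_volumes(7 * x, 7 * y), jaccard_volumes(x, y))
  expect_error(jaccard_volumes(c(1, -1), c(1, 1)), "positive")
})

test_that("percentage errors are signed and relative to the truth", {
  expect_equal(percentage_error(100, 100), 0)
  expect_equal(percentage_error(105, 100), 5)
  expect_equal(percentage_error(0.9e6, 1e6), -10)
  expect_equal(percentage_error(c(110, 90), 100), c(10, -10))
  expect_error(percentage_error(1, 0), "positive")
})

test_that("combination sampling is uniform, reproducible and degenerate at n=1", {
  expect_true(all(sample_combinations(5, 1, 100, seed = 1) == 0))
  a <- sample_combinations(6, 7, 500, seed = 99)
  b <- sample_combinations(6, 7, 500, seed = 99)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 6))
  # per-subject offset frequencies at spacing 2 pass a chi-square test
  cc <- sample_combinations(5, 2, 4000, seed = 3)
  for (i in 1:5) {
    tab <- table(factor(cc[i, ], levels = 0:1))
    expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  }
  # the draw does not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(sample_combinations(3, 4, 10, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("paired interpolator comparison matches the closed-form t-test", {
  cohort <- make_tiny_cohort(n_female = 4, n_male = 3, seed = 21)
  res <- compare_interpolators(cohort, spacing = c(12, 30))
  expect_equal(nrow(res), 2)
  # recompute per-subject MAPEs directly and apply the textbook formula
  profiles <- cohort[cohort$orientation == "sagittal", ]
  mape <- function(p, s, m) {
    truth <- profile_volume(p)
    est <- estimate_icv(p, s, method = m, warn_negative = FALSE)
    mean(abs(100 * (est$value_mm3 - truth) / truth))
  }
  for (s in c(12, 30)) {
    d <- vapply(profiles$profile, function(p) {
      mape(p, s, "constant") - mape(p, s, "spline")
    }, numeric(1))
    tstat <- mean(d) / (sd(d) / sqrt(length(d)))
    pval <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
    row <- res[res$spacing_mm == s, ]
    expect_equal(row$mean_diff, mean(d), tolerance = 1e-12)
    expect_equal(row$statistic, tstat, tolerance = 1e-12)
    expect_equal(row$p_value, pval, tolerance = 1e-12)
    half <- stats::qt(0.975, length(d) - 1) * sd(d) / sqrt(length(d))
    expect_equal(row$conf_low, mean(d) - half, tolerance = 1e-10)
    expect_equal(row$conf_high, mean(d) + half, tolerance = 1e-10)
  }
})

test_that("evaluation at spacing 1 is perfect for constant and linear", {
  cohort <- make_tiny_cohort(seed = 22)
  ev <- evaluate_validity(cohort, spacings = 1, orientations = "sagittal",
                          methods = c("constant", "linear"), count = 50,
                          seed = 4)
  perf <- ev$percentiles
  expect_true(all(perf$value[perf$metric == "icc"] == 1))
  expect_true(all(perf$value[perf$metric == "jaccard"] == 1))
  expect_true(all(abs(perf$value[perf$metric == "pct_error"]) < 1e-10))
})

test_that("the report holds every setting, percentile and metric cell", {
  cohort <- make_tiny_cohort(seed = 23)
  ev <- evaluate_validity(cohort, spacings = c(4, 8),
                          orientations = c("sagittal", "transversal"),
                          methods = c("constant", "spline"),
                          count = 100, seed = 5)
  expect_equal(nrow(ev$percentiles), 2 * 2 * 2 * 5 * 5)
  expect_true(all(ev$summary$n[ev$summary$metric == "icc"] == 100))
  expect_true(all(
    ev$summary$n[ev$summary$metric == "pct_error"] == 100 * 5
  ))
  # percentile curves are non-decreasing in the percentile order
  mono <- ev$percentiles |>
    dplyr::group_by(spacing_mm, orientation, method, metric) |>
    dplyr::summarise(ok = !is.unsorted(value[order(percentile)]),
                     .groups = "drop")
  expect_true(all(mono$ok))
  expect_equal(nrow(ev$paired), 2 * 2)
  expect_equal(glance(ev)$n_settings, 8)
  expect_equal(nrow(tidy(ev)), nrow(ev$percentiles))
})

test_that("evaluation is deterministic and method order has no effect", {
  cohort <- make_tiny_cohort(seed = 24)
  e1 <- evaluate_validity(cohort, spacings = 6, orientations = "coronal",
                          methods = c("constant", "spline"), count = 80,
                          seed = 9)
  e2 <- evaluate_validity(cohort, spacings = 6, orientations = "coronal",
                          methods = c("spline", "constant"), count = 80,
                          seed = 9)
  a1 <- dplyr::arrange(e1$percentiles, method, metric, percentile)
  a2 <- dplyr::arrange(e2$percentiles, method, metric, percentile)
  expect_equal(a1, a2)
})

test_that("Monte-Carlo ICCs land on the exhaustively enumerated values", {
  # 3 subjects at spacing 2: the combination space has exactly 2^3 members
  cohort <- make_tiny_cohort(n_female = 2, n_male = 1, seed = 25)
  profiles <- cohort$profile[cohort$orientation == "sagittal"]
  truth <- vapply(profiles, profile_volume, numeric(1))
  E <- vapply(profiles, function(p) {
    estimate_icv(p, 2, method = "constant")$value_mm3
  }, numeric(2)) # 2 offsets x 3 subjects
  grid <- expand.grid(k1 = 1:2, k2 = 1:2, k3 = 1:2)
  exhaustive <- apply(grid, 1, function(k) {
    y <- c(E[k[1], 1], E[k[2], 2], E[k[3], 3])
    icc_single_absolute(truth, y)
  })
  ev <- evaluate_validity(cohort, spacings = 2, orientations = "sagittal",
                          methods = "constant", count = 4000, seed = 31)
  med <- ev$percentiles$value[ev$percentiles$metric == "icc" &
                                ev$percentiles$percentile == 50]
  expect_gte(med, min(exhaustive))
  expect_lte(med, max(exhaustive))
  expect_equal(med, stats::median(exhaustive), tolerance = 1e-3)
  mean_mc <- ev$summary$mean[ev$summary$metric == "icc"]
  expect_equal(mean_mc, mean(exhaustive), tolerance = 1e-3)
})
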
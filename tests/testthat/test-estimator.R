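test_that("offset subsamples count, start and partition the support", {
  p <- as_area_profile(
    data.frame(position_mm = 0:14, area_mm2 = c(0, 0, rep(10, 10), 0, 0, 0)),
    "sagittal"
  )
  # spacing 1: a single subsample containing every support slice
  s1 <- enumerate_subsamples(p, 1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$subsample[[1]]$positions, 2:11)
  # support of length 10, spacing 4: first positions at support start + 0:3
  s4 <- enumerate_subsamples(p, 4)
  expect_equal(nrow(s4), 4)
  expect_equal(vapply(s4$subsample, function(s) s$positions[1], numeric(1)),
               2 + 0:3)
  # partition property: every spacing splits the support exactly once
  for (n in c(2, 3, 5, 7, 10)) {
    subs <- enumerate_subsamples(p, n)
    expect_equal(nrow(subs), n)
    all_pos <- sort(unlist(lapply(subs$subsample, `[[`, "positions")))
    expect_equal(all_pos, 2:11)
  }
  expect_error(enumerate_subsamples(p, 11), "support")
  expect_error(enumerate_subsamples(p, 0.5), "integer")
})

test_that("zero pads sit one voxel outside the vault on each side", {
  pos <- 0:200
  areas <- ifelse(pos >= 20 & pos <= 150, 100, 0)
  p <- as_area_profile(data.frame(position_mm = pos, area_mm2 = areas),
                       "coronal")
  sub <- pad_zeros(enumerate_subsamples(p, 7)$subsample[[3]], p)
  expect_equal(sub$pad_positions, c(19, 151))
  expect_false(any(sub$pad_positions %in% sub$positions))
})

test_that("piecewise constant estimates are sums times spacing", {
  one <- as_area_profile(
    data.frame(position_mm = 0:40, area_mm2 = c(rep(0, 20), 100, rep(0, 20))),
    "sagittal"
  )
  est <- estimate_icv(one, 1, method = "constant")
  expect_equal(est$value_mm3, 100)
  sub5 <- enumerate_subsamples(one, 1)$subsample[[1]]
  sub5$spacing <- 5 # one ICA of 100 mm^2 at spacing 5 -> 500 mm^3
  expect_equal(estimate_constant(sub5)$value_mm3, 500)
})

test_that("spacing-1 constant and padded-linear estimates are exact", {
  set.seed(10)
  for (rep in 1:5) {
    p <- generate_profile(runif(1, 1.2e6, 1.8e6), extent = sample(80:150, 1),
                          irregularity = runif(1, 0, 0.2))
    truth <- profile_volume(p)
    est <- estimate_icv(p, 1, method = c("constant", "linear"))
    expect_equal(est$value_mm3[est$method == "constant"], truth)
    expect_equal(est$value_mm3[est$method == "linear"], truth)
  }
})

test_that("minimal padded-linear case integrates the two end triangles", {
  # single selected ICA `a` at distances d1, d2 from the pads
  p <- as_area_profile(
    data.frame(position_mm = 0:10, area_mm2 = c(0, rep(60, 9), 0)),
    "sagittal"
  )
  sub <- enumerate_subsamples(p, 9)$subsample[[4]]
  expect_length(sub$areas, 1)
  sub <- pad_zeros(sub, p)
  d1 <- sub$positions[1] - sub$pad_positions[1]
  d2 <- sub$pad_positions[2] - sub$positions[1]
  expect_equal(estimate_linear(sub)$value_mm3, 60 * (d1 + d2) / 2)
})

test_that("linear interpolation underestimates a concave elliptical profile", {
  p <- make_ellipse_profile()
  truth <- profile_volume(p)
  est <- estimate_icv(p, 20, method = "linear")
  expect_true(all(est$value_mm3 < truth))
})

test_that("dense spline estimates converge on the true volume", {
  p <- generate_profile(1.5e6, extent = 136, irregularity = 0.03, seed = 12)
  truth <- profile_volume(p)
  sp1 <- estimate_icv(p, 1, method = "spline")
  expect_equal(sp1$value_mm3, truth, tolerance = 0.005)
  # all three methods agree within 1% at spacing 2 on a smooth phantom
  est2 <- estimate_icv(p, 2)
  expect_lt(max(abs(est2$value_mm3 - truth) / truth), 0.01)
})

test_that("the dispatcher is definitionally equal to the manual pipeline", {
  p <- make_ellipse_profile()
  n <- 13; k <- 4
  sub <- enumerate_subsamples(p, n)$subsample[[k + 1]]
  expect_equal(
    estimate_icv(p, n, offset = k, method = "linear")$value_mm3,
    estimate_linear(pad_zeros(sub, p))$value_mm3
  )
  expect_equal(
    estimate_icv(p, n, offset = k, method = "spline")$value_mm3,
    estimate_spline(pad_zeros(sub, p), warn_negative = FALSE)$value_mm3
  )
  expect_equal(
    estimate_icv(p, n, offset = k, method = "constant")$value_mm3,
    estimate_constant(sub)$value_mm3
  )
  expect_error(estimate_icv(p, n, offset = n), "offset")
  expect_error(estimate_icv(p, n, method = "pchip"), "arg")
  # provenance fields travel with the estimate
  rec <- estimate_icv(p, n, offset = k, method = "spline")
  expect_equal(rec$offset, k)
  expect_equal(rec$spacing_mm, n)
  expect_equal(rec$orientation, "sagittal")
  expect_equal(rec$subject_id, "ellipse")
})

test_that("estimates are invariant under translation of the profile", {
  p <- generate_profile(1.4e6, extent = 90, irregularity = 0.1, seed = 13)
  shifted <- as_area_profile(
    data.frame(position_mm = p$position_mm + 37, area_mm2 = p$area_mm2),
    profile_orientation(p)
  )
  for (n in c(3, 11, 25)) {
    e1 <- estimate_icv(p, n, warn_negative = FALSE)
    e2 <- estimate_icv(shifted, n, warn_negative = FALSE)
    expect_equal(e2$value_mm3, e1$value_mm3, tolerance = 1e-10)
  }
})

test_that("reversing a profile permutes but preserves the offset estimates", {
  p <- generate_profile(1.4e6, extent = 90, irregularity = 0.1, seed = 14)
  reversed <- as_area_profile(
    data.frame(position_mm = p$position_mm, area_mm2 = rev(p$area_mm2)),
    profile_orientation(p)
  )
  for (n in c(4, 9, 20)) {
    for (m in c("constant", "linear", "spline")) {
      e1 <- sort(estimate_icv(p, n, method = m, warn_negative = FALSE)$value_mm3)
      e2 <- sort(estimate_icv(reversed, n, method = m,
                              warn_negative = FALSE)$value_mm3)
      expect_equal(e2, e1, tolerance = 1e-10)
    }
  }
})

test_that("spline estimates warn when the interpolant dips below zero", {
  # a sharp shoulder next to the zero pad forces an undershoot
  p <- as_area_profile(
    data.frame(position_mm = 0:60,
               area_mm2 = c(rep(4000, 50), rep(0, 11))),
    "transversal"
  )
  expect_warning(
    estimate_icv(p, 25, offset = 24, method = "spline"),
    class = "icvsparse_negative_spline"
  )
  expect_silent(estimate_icv(p, 25, method = "spline", warn_negative = FALSE))
})
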
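test_that("consecutive changes follow the time-point order and bridge gaps", {
  p <- make_pairs(ref = c(4.0, 3.0, 3.5), test = c(4.1, 3.2, 3.4),
                  subject_id = "S1",
                  timepoint = c("baseline", "rosc15", "rosc30"))
  d <- consecutive_changes(p, "ci")
  expect_equal(d$delta_ref, c(-1.0, 0.5))
  expect_equal(d$from_timepoint, c("baseline", "rosc15"))
  expect_equal(d$to_timepoint, c("rosc15", "rosc30"))

  # only baseline: nothing to difference
  expect_equal(nrow(consecutive_changes(make_pairs(4, 4.1,
                                                   subject_id = "S1"), "ci")),
               0)

  # missing rosc15: one delta spanning the gap
  p <- make_pairs(ref = c(4.0, 3.0), test = c(4.0, 3.0), subject_id = "S1",
                  timepoint = c("baseline", "rosc30"))
  d <- consecutive_changes(p, "ci")
  expect_equal(nrow(d), 1)
  expect_equal(d$delta_ref, -1.0)
  expect_equal(d$from_timepoint, "baseline")
  expect_equal(d$to_timepoint, "rosc30")
})

test_that("the polar transform measures deviation from the identity line", {
  pt <- function(dr, dt) {
    polar_transform(tibble::tibble(delta_ref = dr, delta_test = dt))
  }
  expect_equal(pt(1, 1)[, c("angle_deg", "radius")],
               tibble::tibble(angle_deg = 0, radius = 1))
  # half-circle reflection of a concordant decrease
  expect_equal(pt(-1, -1)[, c("angle_deg", "radius")],
               tibble::tibble(angle_deg = 0, radius = 1))
  # hand trigonometry: atan2(1, 2) = 26.57 deg
  p <- pt(2, 1)
  expect_equal(p$angle_deg, atan2(1, 2) * 180 / pi - 45, tolerance = 1e-12)
  expect_equal(round(p$angle_deg, 2), -18.43)
  expect_equal(p$radius, 1.5)
  # discordant null-mean change: radius 0
  expect_equal(pt(1, -1)$radius, 0)
  # double zero: angle 0 by convention
  expect_equal(pt(0, 0)$angle_deg, 0)
  # angles stay in (-90, 90]
  set.seed(1)
  p <- pt(rnorm(500), rnorm(500))
  expect_true(all(p$angle_deg > -90 & p$angle_deg <= 90))
})

test_that("the exclusion threshold is a fraction of the reference mean", {
  p <- make_pairs(ref = c(4.4, 4.6), test = c(4.0, 4.0))
  expect_equal(exclusion_threshold(p, "ci", fraction = 0.10), 0.45)
  expect_equal(exclusion_threshold(p, "ci", fraction = 0), 0)
  expect_equal(exclusion_threshold(p, "ci", absolute = 1.0), 1.0)
  expect_error(exclusion_threshold(p[0, ], "ci"), "no usable pairs")
})

test_that("polar statistics: mean deviation, concordance, and boundaries", {
  pts <- tibble::tibble(angle_deg = c(0, 20, -40), radius = c(1, 1, 1))
  s <- polar_statistics(pts)
  expect_equal(s$mean_angular_deviation, -20 / 3, tolerance = 1e-12)
  expect_equal(s$concordance_pct, 100 * 2 / 3, tolerance = 1e-12)
  expect_false(s$good_trending)

  # all on the axis: perfect concurrence
  s <- polar_statistics(tibble::tibble(angle_deg = c(0, 0), radius = c(1, 2)))
  expect_equal(s$concordance_pct, 100)
  expect_true(s$good_trending)

  # |angle| exactly 30 counts as concordant; 31 does not
  expect_equal(polar_statistics(tibble::tibble(angle_deg = 30,
                                               radius = 1))$concordance_pct,
               100)
  expect_equal(polar_statistics(tibble::tibble(angle_deg = 31,
                                               radius = 1))$concordance_pct,
               0)

  # exclusion is strict: at the threshold a point stays in
  s <- polar_statistics(tibble::tibble(angle_deg = c(0, 0),
                                       radius = c(0.45, 0.449)),
                        threshold = 0.45)
  expect_equal(s$n_included, 1)
  expect_equal(s$n_excluded, 1)
  expect_equal(s$n_deltas, s$n_included + s$n_excluded)

  # nothing included: counts only, statistics flagged unavailable
  s <- polar_statistics(tibble::tibble(angle_deg = 0, radius = 0.1),
                        threshold = 1)
  expect_equal(s$n_included, 0)
  expect_true(is.na(s$mean_angular_deviation))
  expect_true(is.na(s$concordance_pct))
})

test_that("perfect trending gives zero angles and full concordance", {
  sim <- simulate_measurements(noiseless_config(n_subjects = 6, p_rosc = 1),
                               seed = 8)
  tr <- trend_analysis(pair_and_filter(sim$records), "ci")
  expect_true(all(abs(tr$points$angle_deg) < 1e-9))
  expect_equal(tr$summary$concordance_pct, 100)
  expect_equal(tr$summary$mean_angular_deviation, 0, tolerance = 1e-9)
  expect_true(tr$summary$good_trending)
})

test_that("trending is invariant to 180-degree reflection and antisymmetric under swap", {
  set.seed(12)
  d <- tibble::tibble(delta_ref = rnorm(200), delta_test = rnorm(200))
  base <- polar_transform(d)

  refl <- polar_transform(dplyr::mutate(d, delta_ref = -delta_ref,
                                        delta_test = -delta_test))
  expect_equal(refl$angle_deg, base$angle_deg)
  expect_equal(refl$radius, base$radius)
  expect_equal(polar_statistics(refl, threshold = 0.2),
               polar_statistics(base, threshold = 0.2))

  swap <- polar_transform(tibble::tibble(delta_ref = d$delta_test,
                                         delta_test = d$delta_ref))
  expect_equal(swap$angle_deg, -base$angle_deg)
  expect_equal(swap$radius, base$radius)
  s1 <- polar_statistics(base, threshold = 0.2)
  s2 <- polar_statistics(swap, threshold = 0.2)
  expect_equal(s2$concordance_pct, s1$concordance_pct)
  expect_equal(s2$mean_angular_deviation, -s1$mean_angular_deviation)
  expect_equal(s2$n_included, s1$n_included)
})
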
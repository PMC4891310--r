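test_that("per-pair differences follow the reference-minus-test convention", {
  p <- make_pairs(ref = c(4.5, 4.5), test = c(4.0, 4.0))
  d <- pair_differences(p, "ci")
  expect_equal(d$diff, c(0.5, 0.5))
  expect_equal(d$mean, c(4.25, 4.25))
  expect_equal(d$pct_diff, c(100 * 0.5 / 4.5, 100 * 0.5 / 4.5))

  # antisymmetry of the sign convention
  d2 <- pair_differences(make_pairs(c(4.0, 4.0), c(4.5, 4.5)), "ci")
  expect_equal(d2$diff, c(-0.5, -0.5))
  d3 <- pair_differences(p, "ci", orientation = "test_minus_ref")
  expect_equal(d3$diff, -d$diff)

  # identical monitors: all differences zero
  d4 <- pair_differences(make_pairs(c(4, 5), c(4, 5)), "ci")
  expect_equal(d4$diff, c(0, 0))

  expect_error(pair_differences(make_pairs(4.5, 4.0), "ci"),
               "insufficient data")
})

test_that("Bland-Altman statistics match hand arithmetic", {
  # differences {-1, 0, 1}: bias 0, SD 1, LoA -1.96 to 1.96
  p <- make_pairs(ref = c(3.833, 4.333, 4.833),
                  test = c(4.833, 4.333, 3.833))
  ba <- bland_altman(p, "ci")
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lo, -1.96)
  expect_equal(ba$loa_hi, 1.96)
  expect_equal(ba$n, 3)
  # bias CI uses the t quantile with n - 1 df
  expect_equal(ba$ci_hi, qt(0.975, 2) / sqrt(3))

  # reference values {4, 5, 6}: CV = 20 %
  ba <- bland_altman(make_pairs(c(4, 5, 6), c(4, 5, 6)), "ci")
  expect_equal(ba$cv_ref, 20)

  # identical monitors: LoA collapse onto a zero bias, zero percentage error
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_lo, ba$loa_hi), c(0, 0))
  expect_equal(ba$pct_error, 0)
  expect_true(ba$acceptable)
})

test_that("percentage error is 1.96 SD over the pooled mean, with a 30 % verdict", {
  pe <- percentage_error(1, 4.333, 4.333)
  expect_equal(pe$pct_error, 100 * 1.96 / 4.333, tolerance = 1e-12)
  expect_equal(round(pe$pct_error, 1), 45.2)
  expect_false(pe$acceptable)

  expect_true(percentage_error(0, 4, 4)$acceptable)
  expect_equal(percentage_error(0, 4, 4)$pct_error, 0)

  # also callable on a bland_altman row
  p <- make_pairs(c(4, 5, 6), c(3.5, 4.5, 5.5))
  ba <- bland_altman(p, "ci")
  expect_equal(percentage_error(ba)$pct_error, ba$pct_error)

  expect_error(percentage_error(1, 0, 0), "not positive")
})

test_that("agreement is scale-equivariant and swap-antisymmetric", {
  set.seed(7)
  ref <- rlnorm(20, log(4), 0.2)
  test <- rlnorm(20, log(4), 0.3)
  ba <- bland_altman(make_pairs(ref, test), "ci")

  # multiplying all values by c scales bias/LoA, leaves pct_error and CV
  ba_c <- bland_altman(make_pairs(3 * ref, 3 * test), "ci")
  expect_equal(ba_c$bias, 3 * ba$bias)
  expect_equal(ba_c$loa_lo, 3 * ba$loa_lo)
  expect_equal(ba_c$loa_hi, 3 * ba$loa_hi)
  expect_equal(ba_c$pct_error, ba$pct_error)
  expect_equal(ba_c$cv_ref, ba$cv_ref)

  # swapping the monitors negates bias, mirrors LoA, keeps pct_error
  ba_s <- bland_altman(make_pairs(test, ref), "ci")
  expect_equal(ba_s$bias, -ba$bias)
  expect_equal(ba_s$loa_lo, -ba$loa_hi)
  expect_equal(ba_s$loa_hi, -ba$loa_lo)
  expect_equal(ba_s$pct_error, ba$pct_error)
})

test_that("the normality gate selects the test pairing and reports itself", {
  # near-perfect linear relation: r = 1 under either correlation
  p <- make_pairs(c(1, 2, 3, 4), c(1.1, 2.1, 3.1, 4.1))
  cmp <- paired_comparison(p, "ci")
  expect_equal(cmp$mean_difference, -0.1)
  expect_equal(cmp$r, 1)
  expect_true(cmp$normality_p_ref > 0.05)

  # identical monitors: mean difference 0, p = 1 on the t branch
  p <- make_pairs(c(1, 2, 3, 4), c(1, 2, 3, 4))
  cmp <- paired_comparison(p, "ci")
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$location_test, "paired_t")
  expect_equal(cmp$location_p, 1)

  # rank reversal: correlation -1
  p <- make_pairs(c(1, 2, 3, 4), c(4, 3, 2, 1))
  cmp <- paired_comparison(p, "ci")
  expect_equal(cmp$r, -1)

  expect_error(paired_comparison(make_pairs(1:2, 2:3), "ci"),
               "insufficient data")
})

test_that("identical differences on the nonparametric branch are a degenerate test", {
  # grossly bimodal values fail the KS gate; a constant shift then leaves
  # the signed-rank test undefined
  ref <- c(rep(1, 20), rep(100, 20))
  test <- ref - 5
  p <- make_pairs(ref, test)
  expect_error(paired_comparison(p, "ci"), "degenerate")
})

test_that("heart rate back-calculates from CI and SVI", {
  expect_equal(back_calculate_hr(3.0, 30), 100)
  expect_equal(back_calculate_hr(4.0, 31.2), 128.2051, tolerance = 1e-6)
  expect_equal(back_calculate_hr(0, 30), 0)
  expect_error(back_calculate_hr(4, -1), "positive")
  expect_error(back_calculate_hr(4, 0), "positive")
})

test_that("back-calculated HR comparison recovers the test monitor's internal rate", {
  sim <- simulate_measurements(noiseless_config(n_subjects = 8, p_rosc = 1),
                               seed = 4)
  pairs <- pair_and_filter(sim$records)
  hb <- hr_backcalc_comparison(pairs)
  # generator defines SVI = 1000 CI / HR, so the identity is exact
  expect_equal(hb$agreement$bias, 0, tolerance = 1e-10)
  expect_equal(hb$agreement$variable, "hr_calc")
  expect_equal(hb$comparison$mean_difference, 0, tolerance = 1e-10)
})

test_that("agreement_table reports thin strata as unavailable", {
  p <- make_pairs(c(4, 5, 6), c(4.2, 5.1, 5.8))  # baseline only
  tab <- agreement_table(p, variables = "ci")
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$available[tab$stratum %in% c("overall", "baseline")]))
  expect_false(any(tab$available[tab$stratum %in% c("rosc15", "rosc30",
                                                    "rosc60")]))
  expect_equal(tab$n[tab$stratum == "rosc15"], 0)
})
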
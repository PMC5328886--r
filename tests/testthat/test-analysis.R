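test_that("transmission regression recovers an exact generating line", {
  x <- c(1, 4, 9, 15, 22, 30)
  tr <- transmission_regression(x, 0.14 + 0.43 * x)
  expect_equal(tr$intercept, 0.14, tolerance = 1e-12)
  expect_equal(tr$slope, 0.43, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-12)
  expect_equal(tr$n_points, 6L)
})

test_that("transmission regression handles flat and degenerate inputs", {
  flat <- transmission_regression(c(1, 5, 9, 14), rep(2.2, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0, tolerance = 1e-12)
  expect_error(transmission_regression(rep(3, 5), 1:5), "degenerate")
  expect_error(transmission_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("cohort deltas are taken against each animal's baseline step", {
  steps <- data.frame(
    animal_id = rep(c("a", "b"), each = 3),
    step_index = rep(0:2, 2),
    iap_cmh2o = c(5, 10, 20, 6, 12, 24),
    ppaw_cmh2o = c(20, 22, 26, 21, 24, 30))
  d <- cohort_deltas(steps)
  expect_equal(nrow(d), 4L)  # baseline rows contribute no delta
  expect_equal(d$delta_iap, c(5, 15, 6, 18))
  expect_equal(d$delta_ppaw, c(2, 6, 3, 9))
  expect_error(cohort_deltas(steps[steps$step_index > 0, ]), "baseline")
})

test_that("finite-difference compliance reproduces reported values", {
  expect_equal(round_half_away(finite_difference_compliance(500, 7.9)), 63)
  expect_equal(round_half_away(finite_difference_compliance(500, 4.4)), 114)
  expect_equal(finite_difference_compliance(0, 3.3), 0)
  expect_error(finite_difference_compliance(500, 0))
  expect_error(finite_difference_compliance(500, -2))
})

test_that("dynamic respiratory compliance is tidal volume over driving pressure", {
  expect_equal(crs_dynamic(331, 20.5, 5.0), 331 / 15.5, tolerance = 1e-12)
  expect_equal(crs_dynamic(300, 35, 5), 10)
  # falls as peak pressure rises at fixed tidal volume and PEEP
  expect_true(all(diff(crs_dynamic(331, c(21, 25, 30, 40), 5)) < 0))
  expect_error(crs_dynamic(331, 5, 5))
  expect_error(crs_dynamic(0, 20, 5))
})

test_that("half-away-from-zero rounding differs from banker's rounding", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5, -2.5)),
               c(1, 2, 3, -1, -3))
  expect_equal(round_half_away(c(40.785, 35.347, 3.678), 1),
               c(40.8, 35.3, 3.7))
})

test_that("grade table rows are internally consistent on any parameters", {
  iap <- exp_params(v = 2.0, k = 2.5, p = 3.8)
  ppaw <- fit_ppaw_curve_params(iap)
  gt <- grade_table(iap, ppaw)
  expect_s3_class(gt, "pv_grade_table")
  expect_equal(gt$grade, c("baseline", "I", "II", "III", "IV"))
  expect_equal(gt$iav_plus_delta_l, gt$additional_iav_l + 0.5)
  expect_equal(gt$iap_after_cmh2o - gt$given_iap_cmh2o, gt$delta_iap_cmh2o)
  expect_equal(gt$given_iap_cmh2o, gt$given_iap_mmhg * 1.3595)
  expect_equal(gt$delta_iap_cmh2o, gt$delta_iap_mmhg * 1.3595,
               tolerance = 1e-12)
  nb <- gt$grade != "baseline"
  expect_equal(gt$cab_ml_per_mmhg[nb] * gt$delta_iap_mmhg[nb],
               rep(500, sum(nb)), tolerance = 1e-9)
  expect_true(is.na(gt$cab_ml_per_mmhg[1L]))
  # convexity: bigger rise and smaller compliance at higher grades
  expect_true(all(diff(gt$delta_iap_cmh2o[nb]) > 0))
  expect_true(all(diff(gt$cab_ml_per_mmhg[nb]) < 0))
  expect_true(all(diff(gt$delta_ppaw_cmh2o[nb]) > 0))
})

test_that("grade table with default curve puts grade I near 7.7 L", {
  pars <- derive_default_iap_params()
  gt <- grade_table(pars, fit_ppaw_curve_params(pars))
  expect_equal(gt$additional_iav_l[gt$grade == "I"], 7.7, tolerance = 0.05)
  expect_equal(gt$additional_iav_l[1L], 0)
})

test_that("grade table degenerate and invalid inputs", {
  pars <- derive_default_iap_params()
  ppaw <- fit_ppaw_curve_params(pars)
  gt0 <- grade_table(pars, ppaw, delta_volume = 0)
  expect_true(all(gt0$delta_iap_cmh2o == 0))
  expect_true(all(is.na(gt0$cab_ml_per_mmhg)))
  expect_error(grade_table(pars, ppaw, grade_thresholds_mmhg = c(16, 12)))
  expect_error(grade_table(pars, ppaw, baseline_iap_mmhg = 13))
  expect_error(grade_table(pars, ppaw, baseline_iap_mmhg = 2))
})

test_that("airway curve composition matches the transmission line", {
  iap <- derive_default_iap_params()
  ppaw <- fit_ppaw_curve_params(iap, baseline_ppaw = 20.5,
                                baseline_iap = 5.0,
                                slope = 0.43, intercept = 0.14)
  V <- seq(0, 11, length.out = 30)
  direct <- 20.5 + 0.14 + 0.43 * (exp_pressure(V, iap) - 5.0)
  expect_equal(exp_pressure(V, ppaw), direct, tolerance = 1e-9)
})
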
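test_that("default IAP parameters satisfy the three anchor conditions", {
  pars <- derive_default_iap_params()
  expect_equal(unclass(pars), frozen_default_params, tolerance = 1e-9)
  expect_equal(exp_pressure(0, pars), 5.0, tolerance = 1e-6)
  expect_equal(exp_pressure(7.7, pars), 16.3, tolerance = 1e-6)
  expect_equal(exp_pressure(10.4, pars), 49.4, tolerance = 1e-6)
})

test_that("anchor solver recovers arbitrary exponential curves", {
  set.seed(13)
  for (i in 1:10) {
    truth <- exp_params(v = runif(1, -2, 4), k = runif(1, 0.5, 4),
                        p = runif(1, -5, 4.5))
    V <- c(0, sort(runif(2, 2, 12)))
    P <- exp_pressure(V, truth)
    got <- exp_params_from_anchors(V, P)
    expect_equal(exp_pressure(V, got), P, tolerance = 1e-6)
  }
  expect_error(exp_params_from_anchors(c(0, 5, 10), c(10, 8, 20)),
               "increase")
})

test_that("animal simulation honours the seeding contract", {
  cfg <- cohort_config(seed = 5)
  a1 <- simulate_animal(cfg, "pig1", seed = 101)
  a2 <- simulate_animal(cfg, "pig1", seed = 101)
  a3 <- simulate_animal(cfg, "pig1", seed = 102)
  expect_identical(a1$steps, a2$steps)
  expect_false(isTRUE(all.equal(a1$steps$iap_cmh2o, a3$steps$iap_cmh2o)))
})

test_that("zero-noise zero-spread simulation round-trips the parameters", {
  cfg <- cohort_config(seed = 2, iap_noise_sd = 0, ppaw_noise_sd = 0,
                       between_animal_sd = 0)
  a <- simulate_animal(cfg, "pig1", seed = 77)
  fit <- pv_fit(a$steps$iap_cmh2o, a$steps$corrected_additional_iav_l,
                "exponential")
  truth <- unclass(cfg$iap_params_mean)
  expect_lt(max(abs(coef(fit) - truth) / abs(truth)), 1e-3)
})

test_that("series obey the stop rule and baseline invariants", {
  co <- simulate_cohort(cohort_config(seed = 4))
  expect_length(co$animals, 7L)
  for (a in co$animals) {
    s <- a$steps
    expect_equal(s$step_index, seq_len(nrow(s)) - 1L)
    expect_equal(s$injected_volume_l[1L], 0)
    expect_equal(s$corrected_additional_iav_l[1L], 0)
    expect_true(all(diff(s$corrected_additional_iav_l) >= 0))
    expect_lt(abs(s$iap_cmh2o[1L] - 5.0), 3)  # baseline approx 5 cmH2O
    expect_gt(s$iap_cmh2o[nrow(s)], 40.8)
    expect_true(all(s$iap_cmh2o[-nrow(s)] <= 40.8))
    expect_true(all(s$ppaw_cmh2o > s$peep_cmh2o))
  }
})

test_that("an unreachable stop pressure is flagged, not an error", {
  cfg <- cohort_config(seed = 6, max_steps = 3L)
  expect_warning(a <- simulate_animal(cfg, "pigX", seed = 8),
                 "did not reach")
  expect_false(a$reached_stop)
  expect_equal(nrow(a$steps), 4L)  # baseline + 3 steps
})

test_that("cohort volumes at stop fall in the plausible per-animal band", {
  co <- simulate_cohort(cohort_config(seed = 12))
  finals <- vapply(co$animals, function(a) {
    utils::tail(a$steps$corrected_additional_iav_l, 1L)
  }, numeric(1))
  expect_true(all(finals > 6 & finals < 16))
})

test_that("simulation is a deterministic function of the configuration", {
  cfg <- cohort_config(seed = 31)
  expect_identical(simulate_cohort(cfg)$steps, simulate_cohort(cfg)$steps)
  cfg0 <- cohort_config(seed = 31, iap_noise_sd = 0, ppaw_noise_sd = 0,
                        between_animal_sd = 0)
  co0a <- simulate_cohort(cfg0)
  co0b <- simulate_cohort(cfg0)
  expect_identical(co0a$steps, co0b$steps)
  # without noise the trajectory is config-determined: seeds are irrelevant
  co0c <- simulate_cohort(cohort_config(seed = 77, iap_noise_sd = 0,
                                        ppaw_noise_sd = 0,
                                        between_animal_sd = 0))
  expect_equal(co0a$steps$iap_cmh2o, co0c$steps$iap_cmh2o)
})

test_that("zero-noise transmission regression returns the generating line", {
  co <- simulate_cohort(cohort_config(seed = 3, iap_noise_sd = 0,
                                      ppaw_noise_sd = 0))
  d <- cohort_deltas(co)
  tr <- transmission_regression(d$delta_iap, d$delta_ppaw)
  expect_equal(tr$intercept, 0.14, tolerance = 1e-9)
  expect_equal(tr$slope, 0.43, tolerance = 1e-9)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)
})

test_that("pooled transmission slope is unbiased across seeds", {
  slopes <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_config(seed = 300 + s))
    d <- cohort_deltas(co)
    transmission_regression(d$delta_iap, d$delta_ppaw)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.43), 0.01)
})

test_that("fitted curves track the generating curves at default noise", {
  # raw (v, k, p) are weakly identified when the asymptote sits close to
  # the baseline pressure, so recovery is asserted on the curve (volume
  # read at reference pressures) at default noise, and on the parameters
  # themselves at small noise where they are identifiable
  err <- c()
  for (s in 1:10) {
    co <- simulate_cohort(cohort_config(seed = 400 + s))
    for (a in co$animals) {
      f <- pv_fit(a$steps$iap_cmh2o, a$steps$corrected_additional_iav_l,
                  "exponential")
      P <- seq(8, 40, length.out = 20)
      Vt <- exp_volume(P, a$true_params)
      Vh <- exp_volume(P, f$params)
      err <- c(err, stats::median(abs(Vh - Vt) / pmax(abs(Vt), 0.5)))
    }
  }
  expect_lt(stats::median(err), 0.05)

  rel <- NULL
  for (s in 1:10) {
    co <- simulate_cohort(cohort_config(seed = 500 + s, iap_noise_sd = 0.1,
                                        ppaw_noise_sd = 0.1))
    for (a in co$animals) {
      f <- pv_fit(a$steps$iap_cmh2o, a$steps$corrected_additional_iav_l,
                  "exponential")
      tr <- unclass(a$true_params)
      rel <- rbind(rel, (coef(f) - tr) / abs(tr))
    }
  }
  expect_true(all(abs(apply(rel, 2, stats::median)) < 0.05))
})

test_that("observed pressures rise monotonically up to noise scale", {
  co <- simulate_cohort(cohort_config(seed = 19))
  for (a in co$animals) {
    drops <- diff(a$steps$iap_cmh2o)
    expect_true(all(drops > -4 * 0.5))  # violations only at noise scale
    expect_true(all(diff(a$true_iap) > 0))
  }
})
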
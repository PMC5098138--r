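# Recovery computation (concentration ratio with instrument-loss correction),
# repeat aggregation, exponential curve fitting and time normalization.

test_that("window mean: constant, ramp, Poisson-consistent uncertainty", {
  tt <- 0:29
  tr <- concentration_trace(tt, rep(4000, 30), source = "reservoir")
  wm <- window_mean(tr, c(5, 25))
  expect_equal(wm$mean, 4000)
  # exact Poisson SD for the counted volume: sqrt(C / (flow * T))
  expect_equal(wm$sd, sqrt(4000 / (1000 / 60 * 20)), tolerance = 1e-12)

  ramp <- concentration_trace(tt, 100 + 10 * tt, source = "reservoir")
  expect_equal(window_mean(ramp, c(0, 29))$mean, 100 + 10 * 14.5)

  pois <- generate_concentration_trace(4000, 20, "reservoir", seed = 8)
  wmp <- window_mean(pois, c(0, 19))
  expect_lt(abs(wmp$mean - 4000), 3 * sqrt(4000 / (1000 / 60 * 19)))

  expect_error(window_mean(tr, c(40, 50)), "outside")
  expect_error(window_mean(tr, c(10, 10)), "end > start")
})

test_that("recovery arithmetic, scale invariance, and the raw-ratio identity", {
  p <- particle_spec(100e-9)
  rec <- measurement_record(4000, 200, p, t_instrument = 2)
  r1 <- compute_recovery(rec, identity_loss_model())
  expect_equal(r1$R, 0.05, tolerance = 1e-12)
  expect_identical(r1$R_raw, r1$R * r1$R_instrument_applied)

  # fixed penetration 0.8 via a model solved for it at t = 2
  D <- diffusion_coefficient(p)$value
  m08 <- loss_model(A = 1, b = log(1 / 0.8) / (D * 2))
  r2 <- compute_recovery(rec, m08)
  expect_equal(r2$R, 0.0625, tolerance = 1e-9)
  expect_equal(r2$R_raw, r2$R * r2$R_instrument_applied, tolerance = 1e-15)

  # concentration-scale invariance is exact
  for (c_scale in c(0.25, 1, 10, 2.5)) {
    rs <- compute_recovery(measurement_record(4000 * c_scale, 200 * c_scale,
                                              p, t_instrument = 2), m08)
    expect_identical(rs$R, r2$R)
  }

  # QC flags
  m_small <- loss_model(A = 1, b = log(1 / 0.05) / (D * 2))  # penetration 0.05
  expect_true("low_confidence" %in%
                compute_recovery(rec, m_small)$qc_flags)
  big <- measurement_record(4000, 5000, p, t_instrument = 2)
  expect_true("qc_fail" %in% compute_recovery(big, identity_loss_model())$qc_flags)
  zero <- measurement_record(0, 200, p, t_instrument = 2)
  expect_error(compute_recovery(zero, identity_loss_model()), "reservoir")
})

test_that("repeat aggregation and repeatability flagging", {
  agg <- aggregate_repeats(c(0.050, 0.052, 0.054))
  expect_equal(agg$mean, 0.052)
  expect_equal(agg$sd, 0.002)
  expect_false(agg$flagged)
  expect_equal(aggregate_repeats(c(0.1, 0.1, 0.1))$sd, 0)
  expect_true(aggregate_repeats(c(0.05, 0.09))$flagged)   # SD > 0.011
  expect_error(aggregate_repeats(0.05), "at least 2")
  expect_error(aggregate_repeats(c(0.05, 0.06),
                                 condition = c("a", "b")), "mix")
})

test_that("exponential curve fit: exact round trip, noisy recovery, degeneracy", {
  t <- c(5, 7, 9, 12, 17, 22)
  R <- 0.3 * exp(-t / 8)
  cv <- fit_recovery_curve(t, R)
  expect_equal(cv$R0, 0.3, tolerance = 1e-6)
  expect_equal(cv$tau, 8, tolerance = 1e-6)

  # 5% noise, n = 12, fixed seed: tau within 10% and agrees with the
  # grid-search oracle
  set.seed(99)
  t12 <- rep(c(5, 7, 9, 12, 17, 22), 2)
  R12 <- 0.3 * exp(-t12 / 8) * (1 + rnorm(12, 0, 0.05))
  cv12 <- fit_recovery_curve(t12, R12)
  expect_lt(abs(cv12$tau - 8) / 8, 0.10)
  gs <- grid_search_exp_fit(t12, R12, R0_range = c(0.2, 0.4),
                            tau_range = c(6, 10))
  expect_equal(cv12$tau, gs$tau, tolerance = 0.02)
  expect_equal(cv12$R0, gs$R0, tolerance = 0.02)

  expect_error(fit_recovery_curve(rep(10, 4), 0.3 * exp(-10 / 8) * rep(1, 4)),
               "degenerate")
  expect_warning(fit_recovery_curve(c(t, 25), c(R, -0.01)), "excluded")
})

test_that("time normalization evaluates the fitted curve at the reference time", {
  cv <- fit_recovery_curve(c(5, 8, 12, 16, 20, 24),
                           0.3 * exp(-c(5, 8, 12, 16, 20, 24) / 8))
  expect_equal(normalize_to_time(cv, 10), 0.3 * exp(-1.25), tolerance = 1e-6)
  expect_equal(normalize_to_time(cv, 0), cv$R0)
  # inside the fitted range the curve interpolates monotonically
  r_lo <- normalize_to_time(cv, 8); r_hi <- normalize_to_time(cv, 12)
  expect_true(r_hi < normalize_to_time(cv, 10) &&
                normalize_to_time(cv, 10) < r_lo)
})

test_that("reservoir stability QC separates stable traces from drifting ones", {
  tt <- 0:29
  expect_true(stability_qc(concentration_trace(tt, rep(4000, 30),
                                               source = "reservoir"))$pass)
  drifting <- concentration_trace(tt, 4000 * (1 + 0.2 * (tt - 14.5) / 29),
                                  source = "reservoir")
  qc <- stability_qc(drifting)
  expect_false(qc$pass)
  expect_equal(qc$drift, 0.2, tolerance = 0.01)
  # pure Poisson counting noise at 4000 cm^-3 passes: exact Poisson CV is
  # sqrt(1 / (C * v)) ~ 0.39% per 1 s sample
  pois <- generate_concentration_trace(4000, 30, "reservoir", seed = 3)
  expect_true(stability_qc(pois)$pass)
})
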
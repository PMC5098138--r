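# The semi-empirical instrument penetration model R = A exp(-b D t):
# evaluation, consistency with the instrument's printed calibration extremes,
# fitting, and persistence.

test_that("penetration evaluates A exp(-b D t) with the expected symmetries", {
  m <- loss_model(A = 1, b = 2.63e7)
  p100 <- particle_spec(100e-9)
  expect_identical(penetration(m, p100, 0), 1)

  # exponent symmetry: halving D at fixed t == halving t at fixed D
  D100 <- diffusion_coefficient(p100)$value
  t0 <- 3
  d_half <- airspace_dummy <- NULL
  p_half_t <- penetration(m, p100, t0 / 2)
  # direct evaluation with halved D
  p_half_D <- m$A * exp(-m$b * (D100 / 2) * t0)
  expect_equal(p_half_t, p_half_D, tolerance = 1e-12)

  expect_error(penetration(m, p100, -1), "non-negative")
  expect_error(loss_model(A = 0, b = 1), "A")
  expect_error(loss_model(A = 1, b = -1), "b")
})

test_that("calibrated model brackets the instrument's printed extremes at plausible transit times", {
  # the instrument's calibration: penetration 0.948 for 100 nm at short
  # passage times and 0.0781 for 22 nm at long passage times
  m <- loss_model(A = 1.00, b = 2.63e7)
  D100 <- diffusion_coefficient(particle_spec(100e-9))$value
  D22 <- diffusion_coefficient(particle_spec(22e-9))$value
  t_short <- log(1 / 0.948) / (m$b * D100)
  t_long <- log(1 / 0.0781) / (m$b * D22)
  expect_gt(t_short, 1); expect_lt(t_short, 5)
  expect_gt(t_long, 1); expect_lt(t_long, 10)
  expect_equal(penetration(m, particle_spec(100e-9), t_short), 0.948,
               tolerance = 1e-10)
  expect_equal(penetration(m, particle_spec(22e-9), t_long), 0.0781,
               tolerance = 1e-10)
})

test_that("fit/evaluate round trip recovers generating parameters on noise-free data", {
  for (pars in list(c(1.00, 2.63e7), c(0.95, 1.5e7), c(1.05, 4e7))) {
    gen <- loss_model(pars[1], pars[2])
    # A > 1 puts noise-free short-transit records above the 1.02 flag level
    rec <- suppressWarnings(generate_calibration_run(gen, noise_cv = 0, seed = 11))
    fit <- suppressWarnings(fit_loss_model(rec))
    expect_equal(fit$A, pars[1], tolerance = 1e-6)
    expect_equal(fit$b, pars[2], tolerance = 1e-6)
    expect_equal(fit$calibration_summary$pearson_r, 1, tolerance = 1e-9)
  }
  # log-space option agrees on noise-free data
  gen <- loss_model(1.00, 2.63e7)
  rec <- generate_calibration_run(gen, noise_cv = 0, seed = 11)
  fit_log <- fit_loss_model(rec, space = "log")
  expect_equal(fit_log$b, 2.63e7, tolerance = 1e-6)
})

test_that("noisy fit recovers parameters within 3% and matches the grid-search oracle", {
  gen <- loss_model(1.00, 2.63e7)
  rec <- generate_calibration_run(gen, flows_Lps = c(0.14, 0.3, 0.75, 1.5, 4.58),
                                  n_rep = 3, noise_cv = 0.01, seed = 4)
  fit <- suppressWarnings(fit_loss_model(rec))
  expect_lt(abs(fit$A - 1.00) / 1.00, 0.03)
  expect_lt(abs(fit$b - 2.63e7) / 2.63e7, 0.03)

  box <- gas_conditions()
  D <- vapply(rec$size_nm * 1e-9, function(d)
    diffusion_coefficient(particle_spec(d), box)$value, numeric(1))
  gs <- grid_search_loss_fit(D * rec$t_instrument_s, rec$R_instrument,
                             A_range = c(0.9, 1.1), b_range = c(2e7, 3.3e7))
  expect_equal(fit$A, gs$A, tolerance = 0.01)
  expect_equal(fit$b, gs$b, tolerance = 0.01)
})

test_that("estimator error shrinks with the number of calibration records", {
  gen <- loss_model(1.00, 2.63e7)
  err_for_n <- function(n_rep, seeds = 1:12) {
    mean(vapply(seeds, function(s) {
      rec <- suppressWarnings(
        generate_calibration_run(gen, n_rep = n_rep, noise_cv = 0.01,
                                 seed = 100 + s))
      fit <- suppressWarnings(fit_loss_model(rec))
      abs(fit$b - 2.63e7) / 2.63e7
    }, numeric(1)))
  }
  e30 <- err_for_n(1)   # 24 records
  e120 <- err_for_n(5)  # 120 records
  expect_lt(e120, e30)
  expect_lt(e120, 0.01)
})

test_that("degenerate calibration designs are rejected with informative errors", {
  gen <- loss_model(1.00, 2.63e7)
  rec <- generate_calibration_run(gen, sizes_nm = c(50, 100), noise_cv = 0, seed = 1)
  one_size <- rec[rec$size_nm == 50, ]
  expect_error(fit_loss_model(one_size), "2 particle sizes")
  one_time <- generate_calibration_run(gen, flows_Lps = 1.5, n_rep = 1,
                                       noise_cv = 0, seed = 1)
  expect_error(fit_loss_model(one_time), "2 passage times")
  expect_error(fit_loss_model(rec[1:3, ]), "at least 4")
})

test_that("passage time is dead volume over phase-mean flows, summed over both legs", {
  expect_equal(passage_time_from_flows(0.6, 0.6, 0.3), 1.0)
  expect_equal(passage_time_from_flows(0.14, 0.14, 0.3), 0.3 / 0.14 * 2,
               tolerance = 1e-12)    # lowest calibration flow: ~4.29 s
  t1 <- passage_time_from_flows(0.5, 0.8, 0.3)
  expect_equal(passage_time_from_flows(1.0, 1.6, 0.3), t1 / 2, tolerance = 1e-12)
  expect_error(passage_time_from_flows(0, 1, 0.3), "flow")
})

test_that("calibration records and fitted models round-trip through CSV/JSON", {
  gen <- loss_model(1.00, 2.63e7)
  rec <- generate_calibration_run(gen, noise_cv = 0.005, seed = 2)
  csv <- tempfile(fileext = ".csv")
  write_calibration_csv(rec, csv)
  rec2 <- read_calibration_csv(csv)
  expect_equal(rec2$R_instrument, rec$R_instrument, tolerance = 1e-12)
  expect_equal(rec2$t_instrument_s, rec$t_instrument_s, tolerance = 1e-12)

  fit <- suppressWarnings(fit_loss_model(rec))
  js <- tempfile(fileext = ".json")
  write_loss_model(fit, js)
  fit2 <- read_loss_model(js)
  expect_equal(fit2$A, fit$A, tolerance = 1e-12)
  expect_equal(fit2$b, fit$b, tolerance = 1e-12)
  expect_equal(fit2$calibration_summary$pearson_r,
               fit$calibration_summary$pearson_r, tolerance = 1e-9)

  # penetration > 1.1 is rejected, > 1.02 flagged
  expect_warning(calibration_records(50, 1, 1, 1, 1.2), "rejected")
  expect_warning(r <- calibration_records(c(50, 50), c(1, 1), c(1, 1),
                                          c(1, 2), c(1.05, 0.9)), "flagged")
  expect_true(r$flagged[1] && !r$flagged[2])
})
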
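# Forward single-breath deposition simulator: kernel composition, limits,
# and the qualitative behaviors seen in measurements (size and hold
# ordering, flow independence, exponential decline).

test_that("pure breath-hold limit reduces to the sphere kernel", {
  # negligible conducting path -> tube penetrations are 1 and the predicted
  # recovery equals the sphere kernel at the maneuver residence time
  tiny <- data.frame(count = 1, length_m = 1e-12)
  g <- lung_geometry(conducting_path = tiny, distal_airspace_radius = 3e-4)
  b <- simulated_breath(particle_spec(75e-9), 12, 12, breath_hold = 10,
                        inhaled_volume = 4.5)
  body <- gas_conditions(temperature = 310.15)
  sim <- simulate_recovery(g, b, body)
  D <- diffusion_coefficient(particle_spec(75e-9), body)$value
  expect_equal(sim$R_pred,
               sphere_remaining_fraction(D, sim$residence_time, 3e-4),
               tolerance = 1e-9)
  expect_equal(sim$penetration_inhale, 1, tolerance = 1e-9)
})

test_that("loss-free limit: zero hold, fast flows, large airspace give R near 1", {
  g <- lung_geometry(distal_airspace_radius = 2e-2)
  b <- simulated_breath(particle_spec(100e-9), 12, 12, breath_hold = 0,
                        inhaled_volume = 4.5)
  expect_gt(simulate_recovery(g, b)$R_pred, 0.99)
})

test_that("recovery orders with particle size and declines with breath hold", {
  g <- lung_geometry()
  r_size <- vapply(c(22, 50, 75, 100), function(s)
    simulate_recovery(g, simulated_breath(particle_spec(s * 1e-9), 1.5, 2,
                                          10))$R_pred, numeric(1))
  expect_true(all(diff(r_size) > 0))
  r_hold <- vapply(c(3, 5, 7, 10, 15, 20), function(h)
    simulate_recovery(g, simulated_breath(particle_spec(50e-9), 1.5, 2,
                                          h))$R_pred, numeric(1))
  expect_true(all(diff(r_hold) < 0))
})

test_that("recovery is nearly flow-independent at fixed residence time", {
  flows <- c(1.2, 2, 4, 7, 10.6)
  g <- lung_geometry()
  r <- vapply(flows, function(q) {
    hold <- breath_hold_for_residence_time(12, 1.5, q)
    simulate_recovery(g, simulated_breath(particle_spec(50e-9), 1.5, q,
                                          hold))$R_pred
  }, numeric(1))
  expect_lt((max(r) - min(r)) / mean(r), 0.05)
})

test_that("log recovery is linear in residence time", {
  g <- lung_geometry()
  sims <- lapply(c(3, 5, 7, 10, 15, 20), function(h)
    simulate_recovery(g, simulated_breath(particle_spec(50e-9), 1.5, 2, h)))
  t <- vapply(sims, `[[`, numeric(1), "residence_time")
  r <- vapply(sims, `[[`, numeric(1), "R_pred")
  expect_gt(summary(stats::lm(log(r) ~ t))$r.squared, 0.999)
})

test_that("cohort predictions: consistency, radius monotonicity, span of printed ranges", {
  g <- lung_geometry()
  single <- cohort_predictions(list(g), data.frame(size_nm = 75, hold_s = 10))
  b <- simulated_breath(particle_spec(75e-9), 1.5, 2, 10)
  expect_equal(single$R_pred, simulate_recovery(g, b)$R_pred, tolerance = 1e-12)
  expect_equal(nrow(single), 1L)

  radii <- c(2e-4, 3e-4, 4e-4)
  r <- vapply(radii, function(rr)
    simulate_recovery(lung_geometry(distal_airspace_radius = rr), b)$R_pred,
    numeric(1))
  expect_true(all(diff(r) > 0))

  # seven airspace radii inverted from the sphere kernel at the bracketing
  # recoveries 0.14 and 0.44 (10 s residence, 100 nm) span that range
  r_lo <- airspace_radius_for_fraction(0.14, particle_spec(100e-9), 10)
  r_hi <- airspace_radius_for_fraction(0.44, particle_spec(100e-9), 10)
  geoms <- lapply(seq(r_lo, r_hi, length.out = 7),
                  function(rr) lung_geometry(distal_airspace_radius = rr))
  hold10 <- breath_hold_for_residence_time(10, 1.5, 2)
  preds <- vapply(geoms, function(gg)
    simulate_recovery(gg, simulated_breath(particle_spec(100e-9), 1.5, 2,
                                           hold10))$R_pred, numeric(1))
  expect_true(all(diff(preds) > 0))
  expect_equal(min(preds), 0.14, tolerance = 0.03)  # tube losses shave ~2%
  expect_equal(max(preds), 0.44, tolerance = 0.03)
})

test_that("simulator input validation", {
  expect_error(simulated_breath(particle_spec(50e-9), 0.05, 2, 10), "0.1-12")
  expect_error(simulated_breath(particle_spec(50e-9), 1.5, 2, -1), ">= 0")
  expect_error(lung_geometry(distal_airspace_radius = -1), "positive")
})
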
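# Breath-trace processing: volume integration, phase detection against
# generator ground truth, residence time, and depth windows.

make_square_trace <- function(inhale_s = 2, inhale_flow = 2, hold_s = 10,
                              exhale_s = 4, exhale_flow = 1, rate = 100) {
  # pre-exhale, inhale, hold, exhale; no noise; used with explicit phases
  dt <- 1 / rate
  seg <- function(dur, val) rep(val, round(dur * rate))
  flow <- c(seg(1, 0), seg(2, -1), seg(inhale_s, inhale_flow), seg(hold_s, 0),
            seg(exhale_s, -exhale_flow), seg(1, 0))
  flow_trace(seq(0, by = dt, length.out = length(flow)), flow)
}

test_that("volume integration is exact for closed-form flows", {
  rate <- 100; dt <- 1 / rate
  tt <- seq(0, 3, by = dt)
  v <- integrate_volume(flow_trace(tt, rep(1, length(tt))))
  expect_equal(v[length(v)], 3.0, tolerance = 1e-12)

  tt4 <- seq(0, 4, by = dt)
  half_sine <- 2 * sin(pi * tt4 / 4)
  v2 <- integrate_volume(flow_trace(tt4, half_sine))
  expect_equal(v2[length(v2)], 16 / pi, tolerance = 1e-4)

  v3 <- integrate_volume(flow_trace(tt, rep(0, length(tt))))
  expect_true(all(v3 == 0))

  # anti-derivative property: differencing recovers flow at interior points
  f <- half_sine
  back <- diff(v2) / dt
  mid <- (f[-1] + f[-length(f)]) / 2
  expect_equal(back, mid, tolerance = 1e-12)

  expect_error(flow_trace(c(0, 0.01, 0.05), c(0, 0, 0)), "uniform")
})

test_that("phase detection recovers generator ground truth", {
  prof <- subject_profile()
  br <- simulated_breath(particle_spec(100e-9), 1.5, 2, breath_hold = 10)
  fl <- generate_flow_trace(prof, br, seed = 5, event_jitter = 0)
  gt <- attr(fl, "ground_truth")
  ph <- detect_phases(fl)
  for (nm in c("II", "III", "IV", "V"))
    expect_lt(abs(ph[[nm]] - gt$phases[[nm]]), 0.010)   # valve events exact
  expect_lt(abs(ph$I - gt$phases[["I"]]), 0.050)        # flow-derived

  # with valve timing imprecision, the realized hold stays within 0.15 s of
  # the commanded duration
  fl_j <- generate_flow_trace(prof, br, seed = 6, event_jitter = 0.1)
  ph_j <- detect_phases(fl_j)
  expect_lt(abs((ph_j$IV - ph_j$III) - 10), 0.15)

  # flat trace is rejected as an invalid maneuver
  flat <- flow_trace(seq(0, 20, by = 0.01), rep(0, 2001))
  expect_error(detect_phases(flat), class = "aidar_maneuver_error")
})

test_that("flow-only phase detection works without valve events", {
  prof <- subject_profile()
  br <- simulated_breath(particle_spec(100e-9), 1.5, 2, breath_hold = 10)
  fl <- generate_flow_trace(prof, br, seed = 5, event_jitter = 0)
  gt <- attr(fl, "ground_truth")
  bare <- flow_trace(fl$sample_times, fl$flow)   # strip valve events
  ph <- detect_phases(bare, collector_volume = gt$collector_volume)
  expect_lt(abs(ph$II - gt$phases[["II"]]), 0.05)
  expect_lt(abs(ph$III - gt$phases[["III"]]), 0.05)
  expect_lt(abs(ph$IV - gt$phases[["IV"]]), 0.05)
  expect_lt(abs(ph$V - gt$phases[["V"]]), 0.05)
})

test_that("residence time follows its definition on a square maneuver", {
  # 2 s constant inhale, 10 s hold, collector (1 L) filled by 1 s of exhale:
  # t_res = 1 + 10 + 0.5 = 11.5 s
  tr <- make_square_trace()
  ph <- maneuver_phases(I = 1, II = 3, III = 5, IV = 15, V = 16)
  expect_equal(residence_time(tr, ph, collector_volume = 1), 11.5,
               tolerance = 0.02)
  # extending the hold extends t_res by exactly the extension
  tr2 <- make_square_trace(hold_s = 14)
  ph2 <- maneuver_phases(I = 1, II = 3, III = 5, IV = 19, V = 20)
  expect_equal(residence_time(tr2, ph2, collector_volume = 1) -
                 residence_time(tr, ph, collector_volume = 1), 4,
               tolerance = 0.02)
  # exhaled volume smaller than the collector: rejection
  expect_error(residence_time(tr, ph, collector_volume = 10),
               class = "aidar_maneuver_error")
})

test_that("generator round trip: residence time and V_i recovered from the trace", {
  prof <- subject_profile()
  for (seed in 1:4) {
    br <- simulated_breath(particle_spec(75e-9), 1.5, 2,
                           breath_hold = c(3, 7, 10, 20)[seed])
    fl <- generate_flow_trace(prof, br, seed = seed, event_jitter = 0)
    gt <- attr(fl, "ground_truth")
    ph <- detect_phases(fl)
    mm <- maneuver_metrics(fl, ph)
    expect_lt(abs(mm$residence_time - gt$residence_time), 0.020)
    expect_lt(abs(mm$V_i - gt$V_i) / gt$V_i, 0.01)
    expect_gt(mm$residence_time, mm$breath_hold_time)
  }
})

test_that("derived metrics are insensitive to sensor noise realizations", {
  prof <- subject_profile()
  br <- simulated_breath(particle_spec(75e-9), 1.5, 2, breath_hold = 10)
  base <- generate_flow_trace(prof, br, seed = 1, event_jitter = 0,
                              noise_sd = 0)
  noisy <- flow_trace(base$sample_times,
                      base$flow + stats::rnorm(length(base$flow), 0, 0.02),
                      valve_events = base$valve_events)
  ph0 <- detect_phases(base); ph1 <- detect_phases(noisy)
  for (nm in c("I", "II", "III", "IV", "V"))
    expect_lt(abs(ph0[[nm]] - ph1[[nm]]), 0.050)
  m0 <- maneuver_metrics(base, ph0); m1 <- maneuver_metrics(noisy, ph1)
  expect_lt(abs(m0$V_i - m1$V_i) / m0$V_i, 0.01)
  expect_lt(abs(m0$residence_time - m1$residence_time), 0.050)
})

test_that("sample depth window follows the last-in-first-sampled convention", {
  expect_equal(sample_depth_window(1.2, 0.3, 0.3), c(1.2, 1.5))
  expect_equal(sample_depth_window(1.2, 1.2, 0.3), c(0.3, 1.5))
  expect_equal(sample_depth_window(1.2, 0.3, 0), c(0.9, 1.2))
  expect_error(sample_depth_window(1.2, 1.3, 0.3), "exceed")
})
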
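# Synthetic-data generator: every input the analysis pipeline needs -
# instrument calibration runs, subject profiles, 100 Hz flow traces realizing
# the single-breath maneuver, and 1 Hz particle-counter traces with Poisson
# counting noise - with complete ground truth recorded separately.

#' Synthetic subject profile
#'
#' A subject is characterized by lung volumes and either an effective distal
#' airspace radius (recovery then comes from the forward simulator) or a
#' prescribed exponential recovery law per particle size (`r0_tau`).
#' Between-repeat physiological variability is modeled as multiplicative
#' lognormal scatter on the true recovery, scaled to a prescribed absolute
#' SD - the instrument's observed repeatability is an absolute band
#' (0.002-0.008, at worst 0.011) across recoveries spanning more than an
#' order of magnitude.
#'
#' @param vital_capacity Vital capacity (L), between 2 and 8. Default 4.5.
#' @param expiratory_reserve Volume exhaled from relaxed end-expiration down
#'   to residual volume in phase I-II (L). Default 1.5.
#' @param dead_space Instrument + anatomical dead space (L). Default 0.3.
#' @param airspace_radius Effective distal airspace radius (m), used when
#'   `r0_tau` is `NULL`. Default 3e-4.
#' @param r0_tau Optional named list per particle size label (e.g. `"100"`)
#'   of `c(R0, tau)` prescribing `R_true(t) = R0 * exp(-t / tau)`.
#' @param repeat_sd Absolute between-repeat SD on R. Default 0.005, the
#'   midpoint of the instrument's typical repeatability band.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(vital_capacity = 4.5, expiratory_reserve = 1.5,
                            dead_space = 0.3, airspace_radius = 3e-4,
                            r0_tau = NULL, repeat_sd = 0.005) {
  if (vital_capacity < 2 || vital_capacity > 8)
    stop("`vital_capacity` must lie in [2, 8] L", call. = FALSE)
  stopifnot(expiratory_reserve > 0, dead_space > 0, airspace_radius > 0,
            repeat_sd >= 0)
  if (!is.null(r0_tau)) {
    stopifnot(is.list(r0_tau), !is.null(names(r0_tau)))
    for (v in r0_tau) stopifnot(length(v) == 2L, all(v > 0))
  }
  structure(list(vital_capacity = vital_capacity,
                 expiratory_reserve = expiratory_reserve,
                 dead_space = dead_space, airspace_radius = airspace_radius,
                 r0_tau = r0_tau, repeat_sd = repeat_sd),
            class = "subject_profile")
}

#' Generate a syringe calibration run
#'
#' Emulates simulated-breathing maneuvers with a calibration syringe through
#' the instrument: for each particle size and flow, the passage time is
#' `V_dead / Q` on each leg (equal flows both ways, 200 ms hold) and the
#' observed penetration is the loss-model prediction times multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param loss Generating [loss_model()].
#' @param sizes_nm Particle sizes (nm). Default `c(22, 50, 75, 100)`.
#' @param flows_Lps Syringe flows (L/s), default six values spanning the
#'   0.14-4.58 L/s calibration range.
#' @param n_rep Repeats per size x flow cell. Default 3.
#' @param noise_cv Multiplicative noise CV (e.g. 0.01 for 1%).
#' @param seed Integer seed; the run is reproducible under it.
#' @param dead_volume Instrument dead volume (L), default 0.3.
#' @param conditions [gas_conditions()] for evaluating D, default the
#'   35 degC box.
#' @return A [calibration_records()] frame (default grid: 4 x 6 x 3 = 72
#'   records) with attribute `ground_truth` holding the generating (A, b).
#' @export
generate_calibration_run <- function(loss, sizes_nm = c(22, 50, 75, 100),
                                     flows_Lps = c(0.14, 0.3, 0.75, 1.5, 3, 4.58),
                                     n_rep = 3, noise_cv = 0.01, seed = 1,
                                     dead_volume = 0.3,
                                     conditions = gas_conditions()) {
  stopifnot(inherits(loss, "loss_model"), noise_cv >= 0, n_rep >= 1)
  grid <- expand.grid(rep = seq_len(n_rep), flow = flows_Lps, size = sizes_nm)
  t_inst <- passage_time_from_flows(grid$flow, grid$flow, dead_volume)
  r_true <- vapply(seq_len(nrow(grid)), function(i)
    penetration(loss, particle_spec(grid$size[i] * 1e-9), t_inst[i], conditions),
    numeric(1))
  withr_seed(seed, {
    noise <- 1 + stats::rnorm(nrow(grid), 0, noise_cv)
  })
  r_obs <- pmin(r_true * noise, 1.1)
  rec <- calibration_records(size_nm = grid$size, flow_in_Lps = grid$flow,
                             flow_ex_Lps = grid$flow, t_instrument_s = t_inst,
                             R_instrument = r_obs)
  attr(rec, "ground_truth") <- list(A = loss$A, b = loss$b, seed = seed,
                                    noise_cv = noise_cv)
  rec
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Generate a synthetic single-breath flow trace
#'
#' Realizes the maneuver at 100 Hz with smooth half-sine flow segments:
#' quiet tidal breathing, exhalation to residual volume (I-II), inhalation of
#' the commanded volume at the commanded mean flow (II-III), breath hold
#' (III-IV), and full exhalation at the commanded mean flow, with the
#' collector valve closing (V) once the collector volume has passed. Gaussian
#' sensor noise (SD 0.02 L/s) is added; valve events are embedded with
#' uniform timing jitter of amplitude `event_jitter` (the valve timing
#' precision, about 100 ms in the reference instrument).
#'
#' @param profile A [subject_profile()].
#' @param breath A [simulated_breath()]; `inhaled_volume` must not exceed the
#'   profile's vital capacity.
#' @param seed Integer seed.
#' @param collector_volume Collector volume (L), default 1.2.
#' @param event_jitter Valve-event jitter amplitude (s), default 0.1. Set to
#'   0 for exactly placed events.
#' @param noise_sd Flow sensor noise SD (L/s), default 0.02.
#' @param sampling_rate Hz, default 100.
#' @return A [flow_trace()] with embedded `valve_events` and attribute
#'   `ground_truth`: list with the true phase times, `V_i`, phase-mean flows,
#'   residence time and passage-time components (all noise-free,
#'   closed-form).
#' @export
generate_flow_trace <- function(profile, breath, seed = 1,
                                collector_volume = 1.2, event_jitter = 0.1,
                                noise_sd = 0.02, sampling_rate = 100) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(breath, "simulated_breath"))
  if (breath$inhaled_volume > profile$vital_capacity)
    stop("infeasible maneuver: inhaled volume exceeds vital capacity",
         call. = FALSE)
  dt <- 1 / sampling_rate
  half_sine <- function(volume, duration) {
    # mean flow = volume / duration; peak = pi/2 * mean
    tseg <- seq(dt, duration, by = dt)
    (volume / duration) * (pi / 2) * sin(pi * (tseg - dt / 2) / duration)
  }

  tidal_vol <- 0.8; tidal_period <- 4; n_tidal <- 2L
  t_in  <- breath$inhaled_volume / breath$inhale_flow
  t_ex  <- breath$inhaled_volume / breath$exhale_flow
  t_erv <- profile$expiratory_reserve / 0.75       # relaxed exhale at 0.75 L/s

  # tidal cycles end on an inhale half so that phase I (start of the
  # exhalation to residual volume) is a genuine flow reversal
  hs <- half_sine(tidal_vol, tidal_period / 2)
  seg_tidal <- rep(hs, times = 2L * n_tidal) *
    rep(rep(c(-1, 1), each = length(hs)), times = n_tidal)
  seg_erv  <- -half_sine(profile$expiratory_reserve, t_erv)
  seg_in   <- half_sine(breath$inhaled_volume, t_in)
  # valve timing imprecision: the realized hold deviates from the commanded
  # duration by up to +/- event_jitter; the embedded events record the
  # realized switching times
  withr_seed(seed, {
    hold_dur <- breath$breath_hold +
      if (event_jitter > 0) stats::runif(1, -event_jitter, event_jitter) else 0
    seg_hold <- rep(0, round(hold_dur / dt))
    seg_ex   <- -half_sine(breath$inhaled_volume, t_ex)
    seg_tail <- rep(0, round(1 / dt))
    flow <- c(seg_tidal, seg_erv, seg_in, seg_hold, seg_ex, seg_tail)
    noise_all <- stats::rnorm(length(flow), 0, noise_sd)
  })
  n <- length(flow)
  tt <- seq(0, by = dt, length.out = n)

  t_I   <- length(seg_tidal) * dt
  t_II  <- t_I + length(seg_erv) * dt
  t_III <- t_II + length(seg_in) * dt
  t_IV  <- t_III + length(seg_hold) * dt
  # collector valve closes when the exhaled half-sine has passed collector_volume
  t_V <- t_IV + (t_ex / pi) * acos(1 - 2 * collector_volume / breath$inhaled_volume)

  events <- c(II = t_II, III = t_III, IV = t_IV, V = t_V)
  trace <- flow_trace(tt, flow + noise_all, valve_events = events)

  q_ex_sample <- collector_volume / (t_V - t_IV)   # mean flow over IV-V
  truth <- list(
    phases = c(I = t_I, II = t_II, III = t_III, IV = t_IV, V = t_V),
    V_i = breath$inhaled_volume,
    breath_hold = hold_dur,
    mean_flow_inhale = breath$inhale_flow,
    mean_flow_exhale_sample = q_ex_sample,
    # half the aerosol is inhaled at the half-sine midpoint; the sample
    # midpoint is where half the collector volume has passed
    residence_time = (t_III - t_II) / 2 + hold_dur +
      (t_ex / pi) * acos(1 - collector_volume / breath$inhaled_volume),
    collector_volume = collector_volume,
    seed = seed)
  attr(trace, "ground_truth") <- truth
  trace
}

#' Generate a particle-counter trace
#'
#' 1 Hz Poisson counting around a (possibly drifting) mean: each sample
#' counts `Poisson(C * counter_flow * dt)` particles in the sampled volume.
#'
#' @param mean_concentration Underlying mean (cm^-3).
#' @param duration Trace length (s).
#' @param source `"reservoir"` or `"sample"`.
#' @param seed Integer seed.
#' @param drift Relative linear drift over the trace (default 0).
#' @param counter_flow Counter flow (cm^3/s), default 1 L/min.
#' @param t0 Time of the first sample (s), default 0.
#' @param counting_noise If `FALSE`, return the underlying mean exactly
#'   (no Poisson sampling). Default `TRUE`.
#' @return A [concentration_trace()].
#' @export
generate_concentration_trace <- function(mean_concentration, duration,
                                         source = c("reservoir", "sample"),
                                         seed = 1, drift = 0,
                                         counter_flow = 1000 / 60, t0 = 0,
                                         counting_noise = TRUE) {
  source <- match.arg(source)
  stopifnot(mean_concentration >= 0, duration >= 2)
  tt <- seq(t0, t0 + duration - 1, by = 1)
  rel <- seq(-0.5, 0.5, length.out = length(tt))
  mu <- mean_concentration * (1 + drift * rel)
  if (counting_noise) {
    withr_seed(seed, {
      counts <- stats::rpois(length(tt), pmax(mu, 0) * counter_flow)
    })
    conc <- counts / counter_flow
  } else {
    conc <- pmax(mu, 0)
  }
  concentration_trace(tt, conc, source = source, counter_flow = counter_flow)
}

#' Generate a complete synthetic measurement session
#'
#' For each condition (particle size, breath hold) and repeat: a flow trace
#' realizing the maneuver; a reservoir concentration trace (Poisson counting
#' noise around the reservoir mean); and a sample-collector trace whose
#' underlying mean is
#' `C_reservoir * R_true * R_instrument_true * exp(repeat noise)`,
#' with `R_true` from the subject's prescribed `(R0, tau)` law evaluated at
#' the true residence time (or from the forward simulator when no law is
#' prescribed) and `R_instrument_true` from the loss model at the true
#' passage time. Ground truth for every measurement is stored in the
#' `ground_truth` element, which the analysis path never reads.
#'
#' @param profile A [subject_profile()].
#' @param conditions A `data.frame` with columns `size_nm` and `hold_s`
#'   (default: the full 4-size x 6-hold study grid).
#' @param loss Generating [loss_model()]; default the calibrated instrument
#'   model `loss_model(1.00, 2.63e7)`.
#' @param reservoir_concentration Reservoir mean (cm^-3), between 500 and
#'   20000. Default 4000.
#' @param n_rep Repeats per condition, default 3.
#' @param seed Integer base seed; per-measurement seeds are derived from it.
#' @param inhale_flow,exhale_flow Commanded mean flows (L/s).
#' @param collector_volume Collector volume (L), default 1.2.
#' @param reservoir_drift Relative reservoir drift per measurement, default 0.
#' @param event_jitter Valve jitter (s) passed to [generate_flow_trace()].
#' @param counting_noise If `FALSE`, concentration traces carry the
#'   underlying means exactly (no Poisson sampling). Default `TRUE`.
#' @return An object of class `synthetic_session`: list with `measurements`
#'   (each holding `flow`, `reservoir`, `sample` traces plus metadata),
#'   `manifest` (conditions table), `ground_truth` (per-measurement true R,
#'   residence time, R_instrument, seeds) and `profile`.
#' @export
generate_session <- function(profile,
                             conditions = expand.grid(size_nm = c(22, 50, 75, 100),
                                                      hold_s = c(3, 5, 7, 10, 15, 20)),
                             loss = loss_model(1.00, 2.63e7),
                             reservoir_concentration = 4000,
                             n_rep = 3, seed = 1,
                             inhale_flow = 1.5, exhale_flow = 2,
                             collector_volume = 1.2,
                             reservoir_drift = 0, event_jitter = 0.1,
                             counting_noise = TRUE) {
  stopifnot(inherits(profile, "subject_profile"), inherits(loss, "loss_model"))
  if (reservoir_concentration < 500 || reservoir_concentration > 20000)
    stop("`reservoir_concentration` must lie in [500, 20000] cm^-3", call. = FALSE)
  stopifnot(all(c("size_nm", "hold_s") %in% names(conditions)))

  body <- gas_conditions(temperature = 310.15)
  measurements <- list(); truth <- list(); rows <- list()
  k <- 0L
  for (i in seq_len(nrow(conditions))) {
    size <- conditions$size_nm[i]; hold <- conditions$hold_s[i]
    for (rep_i in seq_len(n_rep)) {
      k <- k + 1L
      mseed <- (seed * 10007L + k * 101L) %% .Machine$integer.max
      breath <- simulated_breath(particle_spec(size * 1e-9), inhale_flow,
                                 exhale_flow, hold,
                                 inhaled_volume = profile$vital_capacity)
      fl <- generate_flow_trace(profile, breath, seed = mseed,
                                collector_volume = collector_volume,
                                event_jitter = event_jitter)
      gt <- attr(fl, "ground_truth")

      R_true <- if (!is.null(profile$r0_tau)) {
        par <- profile$r0_tau[[as.character(size)]]
        if (is.null(par))
          stop(sprintf("no (R0, tau) prescribed for size %g nm", size),
               call. = FALSE)
        par[1] * exp(-gt$residence_time / par[2])
      } else {
        sphere_remaining_fraction(
          diffusion_value(breath$particle, body),
          gt$residence_time, profile$airspace_radius)
      }
      t_inst_true <- passage_time_from_flows(gt$mean_flow_inhale,
                                             gt$mean_flow_exhale_sample)
      r_inst_true <- penetration(loss, breath$particle, t_inst_true)

      # between-repeat lognormal variability with absolute SD repeat_sd on R
      withr_seed(mseed + 1L, {
        sdlog <- if (R_true > 0) min(profile$repeat_sd / R_true, 0.5) else 0
        R_meas <- R_true * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
      })

      res <- generate_concentration_trace(reservoir_concentration, 30,
                                          "reservoir", seed = mseed + 2L,
                                          drift = reservoir_drift,
                                          t0 = gt$phases[["II"]] - 29,
                                          counting_noise = counting_noise)
      smp <- generate_concentration_trace(
        reservoir_concentration * R_meas * r_inst_true, 15, "sample",
        seed = mseed + 3L, t0 = gt$phases[["V"]] + 2,
        counting_noise = counting_noise)

      id <- sprintf("m%03d", k)
      measurements[[id]] <- list(
        id = id, size_nm = size, hold_s = hold, rep = rep_i,
        flow = fl, reservoir = res, sample = smp,
        reservoir_window = c(gt$phases[["II"]] - 20, gt$phases[["II"]]),
        sample_window = c(gt$phases[["V"]] + 2, gt$phases[["V"]] + 12))
      truth[[id]] <- list(R_true = R_true, R_measured = R_meas,
                          residence_time = gt$residence_time,
                          R_instrument = r_inst_true,
                          t_instrument = t_inst_true, seed = mseed)
      rows[[k]] <- data.frame(id = id, size_nm = size, hold_s = hold, rep = rep_i)
    }
  }
  structure(list(measurements = measurements,
                 manifest = do.call(rbind, rows),
                 ground_truth = truth,
                 profile = profile,
                 loss = loss,
                 seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic session: %d measurements (%d conditions), seed %d\n",
              nrow(x$manifest),
              nrow(unique(x$manifest[c("size_nm", "hold_s")])), x$seed))
  invisible(x)
}
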
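# Breath-trace processing: volume integration, maneuver phase detection
# (points I-V of the single-breath protocol), end-inspiratory volume,
# residence time and volumetric lung-depth windows.
#
# Protocol: after quiet breathing of particle-free air the subject exhales to
# residual volume (I -> II), inhales test aerosol to total lung capacity
# (II -> III), holds breath (III -> IV), then exhales into the sample
# collector until the commanded volume has passed (IV -> V), continuing to
# waste afterwards.

#' Pneumotachograph flow trace
#'
#' @param sample_times Sample times (s), uniform grid (nominally 100 Hz).
#' @param flow Signed flow (L/s); positive = inhalation. Must satisfy
#'   `|flow| < 15` and be finite.
#' @param valve_events Optional named numeric vector of valve-event
#'   timestamps, names among `"II", "III", "IV", "V"`. When present they
#'   override flow-derived phase timestamps.
#' @return An object of class `flow_trace`.
#' @export
flow_trace <- function(sample_times, flow, valve_events = NULL) {
  if (length(sample_times) != length(flow) || length(flow) < 2L)
    stop("`sample_times` and `flow` must be equal-length vectors (>= 2)",
         call. = FALSE)
  dt <- diff(sample_times)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop("`sample_times` must be a strictly increasing uniform grid",
         call. = FALSE)
  if (any(!is.finite(flow)) || any(abs(flow) >= 15))
    stop("`flow` must be finite with |flow| < 15 L/s", call. = FALSE)
  if (!is.null(valve_events)) {
    stopifnot(is.numeric(valve_events), !is.null(names(valve_events)),
              all(names(valve_events) %in% c("I", "II", "III", "IV", "V")))
  }
  structure(list(sample_times = as.numeric(sample_times),
                 flow = as.numeric(flow),
                 dt = stats::median(dt),
                 valve_events = valve_events),
            class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("Flow trace: %d samples at %.0f Hz (%.1f s), flow in [%.2f, %.2f] L/s\n",
              length(x$flow), 1 / x$dt, diff(range(x$sample_times)),
              min(x$flow), max(x$flow)))
  if (!is.null(x$valve_events))
    cat("  valve events:", paste(sprintf("%s=%.2fs", names(x$valve_events),
                                         x$valve_events), collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative inhaled volume
#'
#' Trapezoidal cumulative integral of the signed flow; the first sample is 0.
#' Differencing the result recovers the flow at interior points to O(dt^2).
#'
#' @param trace A [flow_trace()].
#' @return Numeric vector (L), same length as the trace.
#' @export
integrate_volume <- function(trace) {
  stopifnot(inherits(trace, "flow_trace"))
  f <- trace$flow
  cumsum(c(0, (f[-1] + f[-length(f)]) / 2)) * trace$dt
}

#' Maneuver phase timestamps
#'
#' @param I,II,III,IV,V Timestamps (s) of: start of exhalation to residual
#'   volume (I), start of aerosol inhalation (II, aerosol valve opens), start
#'   of breath hold (III, all valves closed), start of sampled exhalation
#'   (IV, collector valve opens), collector valve closure (V).
#' @return An object of class `maneuver_phases`.
#' @export
maneuver_phases <- function(I, II, III, IV, V) {
  ts <- c(I = I, II = II, III = III, IV = IV, V = V)
  if (any(!is.finite(ts)) || any(diff(ts) <= 0))
    stop(maneuver_error("phase timestamps must be finite and strictly increasing I < II < III < IV < V"))
  structure(as.list(ts), class = "maneuver_phases")
}

#' @export
print.maneuver_phases <- function(x, ...) {
  cat(sprintf("Maneuver phases (s): I=%.2f II=%.2f III=%.2f IV=%.2f V=%.2f\n",
              x$I, x$II, x$III, x$IV, x$V))
  cat(sprintf("  breath hold III->IV: %.2f s\n", x$IV - x$III))
  invisible(x)
}

# structured rejection error: the measurement is invalid, not the code
maneuver_error <- function(msg) {
  errorCondition(paste0("maneuver rejected: ", msg),
                 class = c("aidar_maneuver_error", "error"))
}

#' Detect maneuver phases from a flow trace
#'
#' The breath hold is located as a sustained near-zero-flow plateau
#' (|flow| < `hold_threshold` L/s on a 50 ms smoothed trace, sustained for at
#' least `min_hold` s, with `hysteresis` L/s on exit) that is preceded by an
#' inhalation and followed by an exhalation. Phases II and I are the
#' preceding exhale-to-inhale and inhale-to-exhale flow zero crossings; IV is
#' the plateau end. V is taken from valve events when present, else from the
#' exhaled volume reaching `collector_volume`, else the end of the
#' exhalation. Valve events, when embedded in the trace, override all
#' flow-derived timestamps.
#'
#' @param trace A [flow_trace()].
#' @param collector_volume Optional commanded collector volume (L), used to
#'   place V when no valve event is available.
#' @param hold_threshold Zero-flow threshold (L/s), default 0.05.
#' @param hysteresis Exit hysteresis (L/s), default 0.02.
#' @param min_hold Minimum plateau duration (s), default 0.3.
#' @return A [maneuver_phases()] object.
#' @export
detect_phases <- function(trace, collector_volume = NULL,
                          hold_threshold = 0.05, hysteresis = 0.02,
                          min_hold = 0.3) {
  stopifnot(inherits(trace, "flow_trace"))
  tt <- trace$sample_times
  n <- length(tt)
  k <- max(1L, round(0.05 / trace$dt))          # 50 ms smoothing for detection
  sm <- stats::filter(trace$flow, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- trace$flow[is.na(sm)]
  sm <- as.numeric(sm)

  # candidate holds: runs with |flow| below threshold (exit above
  # threshold + hysteresis), lasting >= min_hold
  low <- abs(sm) < hold_threshold
  high <- abs(sm) > hold_threshold + hysteresis
  runs <- find_holds(low, high)
  runs <- runs[(tt[runs[, 2L]] - tt[runs[, 1L]]) >= min_hold, , drop = FALSE]
  if (nrow(runs) == 0L)
    stop(maneuver_error("no breath-hold plateau found"))

  hold <- NULL
  for (i in rev(seq_len(nrow(runs)))) {   # prefer the last qualifying hold
    s <- runs[i, 1L]; e <- runs[i, 2L]
    before <- sm[max(1L, s - round(0.5 / trace$dt)):s]
    after  <- sm[e:min(n, e + round(0.5 / trace$dt))]
    if (max(before) > 3 * hold_threshold && min(after) < -3 * hold_threshold) {
      hold <- c(s, e); break
    }
  }
  if (is.null(hold))
    stop(maneuver_error("no plateau bounded by an inhalation and an exhalation"))

  iii <- hold[1L]; iv <- hold[2L]
  # II: walk back through the inhalation (and any leading hold samples) to
  # the last clearly-negative (exhale) sample; II is the sample after it.
  ii <- segment_start_before(sm, iii, stop_when = function(v) v < -hold_threshold)
  if (is.na(ii)) stop(maneuver_error("no inhalation onset (II) before the hold"))
  ii <- refine_to_crossing(sm, ii, rising = TRUE)
  # I: walk back through the exhalation to the last clearly-positive sample.
  i1 <- segment_start_before(sm, ii - 1L, stop_when = function(v) v > hold_threshold)
  if (is.na(i1)) stop(maneuver_error("no exhalation onset (I) before inhalation"))
  i1 <- refine_to_crossing(sm, i1, rising = FALSE)

  t_I <- tt[i1]; t_II <- tt[ii]; t_III <- tt[iii]; t_IV <- tt[iv]
  t_V <- NA_real_
  if (is.null(trace$valve_events) || !("V" %in% names(trace$valve_events))) {
    vol <- integrate_volume(trace)
    ex <- stats::approx(tt, vol, xout = t_IV, rule = 2)$y - vol  # exhaled since IV
    ex[tt < t_IV] <- 0
    if (!is.null(collector_volume)) {
      idx <- which(ex >= collector_volume)
      if (length(idx) == 0L)
        stop(maneuver_error("exhaled volume never reaches the collector volume"))
      t_V <- stats::approx(ex[(idx[1L] - 1L):idx[1L]],
                           tt[(idx[1L] - 1L):idx[1L]],
                           xout = collector_volume)$y
    } else {
      idx <- which(tt > t_IV + min_hold & abs(sm) < hold_threshold)
      t_V <- if (length(idx) > 0L) tt[idx[1L]] else tt[n]
    }
  }

  ev <- trace$valve_events
  if (!is.null(ev)) {
    if ("II" %in% names(ev)) t_II <- ev[["II"]]
    if ("III" %in% names(ev)) t_III <- ev[["III"]]
    if ("IV" %in% names(ev)) t_IV <- ev[["IV"]]
    if ("V" %in% names(ev)) t_V <- ev[["V"]]
  }
  maneuver_phases(t_I, t_II, t_III, t_IV, t_V)
}

# runs of TRUE in `low`, terminated by TRUE in `high`; returns start/end index
find_holds <- function(low, high) {
  n <- length(low)
  out <- matrix(integer(0), ncol = 2L)
  i <- 1L
  while (i <= n) {
    if (low[i]) {
      j <- i
      while (j < n && !high[j + 1L]) j <- j + 1L
      out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# walk backwards from index `at` until `stop_when(sm[i])` holds; the segment
# of interest starts at the following sample. NA if the trace start is hit.
segment_start_before <- function(sm, at, stop_when) {
  i <- at
  while (i > 1L && !isTRUE(stop_when(sm[i]))) i <- i - 1L
  if (i <= 1L) NA_integer_ else i + 1L
}

# nudge a threshold-based boundary forward to the actual zero crossing of
# the smoothed flow (rising = exhale -> inhale transition)
refine_to_crossing <- function(sm, i, rising) {
  n <- length(sm)
  if (rising) { while (i < n && sm[i] < 0) i <- i + 1L }
  else        { while (i < n && sm[i] > 0) i <- i + 1L }
  i
}

#' Per-breath maneuver metrics
#'
#' Computes the end-inspiratory inhaled volume `V_i` (volume integral over
#' II -> III, i.e. the inspired volume from residual volume to total lung
#' capacity), breath-hold time, residence time, collector volume, phase-mean
#' flows, and the volumetric lung-depth window of the analyzed sample slice.
#'
#' @param trace A [flow_trace()].
#' @param phases A [maneuver_phases()], e.g. from [detect_phases()].
#' @param collector_volume Collector volume (L). If `NULL`, the exhaled
#'   volume between IV and V is used.
#' @param analyzed_volume Volume of the analyzed slice drawn from the top of
#'   the collector (L), default 0.3.
#' @param dead_space Dead space between mouth and collector, including
#'   anatomical dead space (L), default 0.3.
#' @return An object of class `maneuver_metrics`: list with `V_i`,
#'   `breath_hold_time`, `residence_time`, `collector_volume`,
#'   `sample_depth_window`, `mean_flow_inhale`, `mean_flow_exhale`.
#' @export
maneuver_metrics <- function(trace, phases, collector_volume = NULL,
                             analyzed_volume = 0.3, dead_space = 0.3) {
  stopifnot(inherits(trace, "flow_trace"), inherits(phases, "maneuver_phases"))
  vol <- integrate_volume(trace)
  tt <- trace$sample_times
  v_at <- function(t) stats::approx(tt, vol, xout = t, rule = 2)$y
  V_i <- v_at(phases$III) - v_at(phases$II)
  if (V_i <= 0) stop(maneuver_error("non-positive inspired volume"))
  v_col <- v_at(phases$IV) - v_at(phases$V)
  if (is.null(collector_volume)) collector_volume <- v_col
  q_in <- V_i / (phases$III - phases$II)
  q_ex <- v_col / (phases$V - phases$IV)
  t_res <- residence_time(trace, phases, collector_volume)
  structure(list(
    V_i = V_i,
    breath_hold_time = phases$IV - phases$III,
    residence_time = t_res,
    collector_volume = collector_volume,
    sample_depth_window = sample_depth_window(collector_volume,
                                              analyzed_volume, dead_space),
    mean_flow_inhale = q_in,
    mean_flow_exhale = q_ex
  ), class = "maneuver_metrics")
}

#' @export
print.maneuver_metrics <- function(x, ...) {
  cat(sprintf("Maneuver: V_i = %.2f L, hold = %.2f s, residence time = %.2f s\n",
              x$V_i, x$breath_hold_time, x$residence_time))
  cat(sprintf("  collector %.2f L, sample depth %.2f-%.2f L, flows %.2f / %.2f L/s\n",
              x$collector_volume, x$sample_depth_window[1],
              x$sample_depth_window[2], x$mean_flow_inhale, x$mean_flow_exhale))
  invisible(x)
}

#' Residence time of the test aerosol in the lung
#'
#' Defined as the time from when half of the test aerosol has been inhaled
#' (cumulative inspired volume since II reaching V_i / 2) to the midpoint
#' time of the exhaled sample (cumulative exhaled volume since IV reaching
#' half the collector volume). Always exceeds the breath-hold duration.
#'
#' @param trace A [flow_trace()].
#' @param phases A [maneuver_phases()].
#' @param collector_volume Collector volume (L).
#' @return Residence time (s).
#' @export
residence_time <- function(trace, phases, collector_volume) {
  stopifnot(inherits(trace, "flow_trace"), inherits(phases, "maneuver_phases"))
  vol <- integrate_volume(trace)
  tt <- trace$sample_times
  v_at <- function(t) stats::approx(tt, vol, xout = t, rule = 2)$y
  V_i <- v_at(phases$III) - v_at(phases$II)

  ins <- tt >= phases$II & tt <= phases$III
  t_half <- crossing_time(tt[ins], vol[ins] - v_at(phases$II), V_i / 2)
  if (is.na(t_half)) stop(maneuver_error("could not locate half-inhaled time"))

  exh <- tt >= phases$IV
  ex_vol <- v_at(phases$IV) - vol[exh]
  t_mid <- crossing_time(tt[exh], ex_vol, collector_volume / 2)
  if (is.na(t_mid))
    stop(maneuver_error("exhaled volume is smaller than the collector volume"))
  t_mid - t_half
}

# first time a monotone-ish series crosses `target`, linearly interpolated
crossing_time <- function(t, v, target) {
  idx <- which(v >= target)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (t[i] - t[i - 1L]) * (target - v[i - 1L]) / (v[i] - v[i - 1L])
}

#' Volumetric lung-depth window of the analyzed sample slice
#'
#' The analyzed slice is drawn from the top (inlet end) of the sample
#' collector, i.e. the last-exhaled, deepest air (last in, first sampled).
#' Its volumetric lung depth — cumulative exhaled volume, including dead
#' space, preceding the sampled parcel — is
#' `[collector - analyzed + dead_space, collector + dead_space]`.
#'
#' @param collector_volume Collector volume (L).
#' @param analyzed_volume Analyzed slice volume (L), <= collector volume.
#' @param dead_space Instrument plus anatomical dead space (L).
#' @return Numeric length-2 vector `[min, max]` (L).
#' @examples
#' sample_depth_window(1.2, 0.3, 0.3) # 1.2 to 1.5 L
#' @export
sample_depth_window <- function(collector_volume, analyzed_volume, dead_space) {
  stopifnot(collector_volume > 0, analyzed_volume > 0, dead_space >= 0)
  if (analyzed_volume > collector_volume)
    stop("`analyzed_volume` cannot exceed `collector_volume`", call. = FALSE)
  c(collector_volume - analyzed_volume + dead_space,
    collector_volume + dead_space)
}
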
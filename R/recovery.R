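# Loss-corrected particle recovery:
#   R = (C_sample / C_reservoir) / R_instrument
# plus repeat aggregation, QC, exponential recovery-vs-residence-time curve
# fitting and time normalization.

#' Particle-counter concentration trace
#'
#' 1 Hz condensation-particle-counter style number-concentration series,
#' tagged by sampling source.
#'
#' @param sample_times Sample times (s), uniform grid (nominally 1 Hz).
#' @param concentration Number concentration (cm^-3), >= 0.
#' @param source `"reservoir"` or `"sample"`.
#' @param counter_flow Counter sampling flow (cm^3/s); default 1 L/min.
#' @return An object of class `concentration_trace`.
#' @export
concentration_trace <- function(sample_times, concentration,
                                source = c("reservoir", "sample"),
                                counter_flow = 1000 / 60) {
  source <- match.arg(source)
  if (length(sample_times) != length(concentration) || length(concentration) < 2L)
    stop("`sample_times` and `concentration` must be equal-length vectors (>= 2)",
         call. = FALSE)
  dt <- diff(sample_times)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop("`sample_times` must be a strictly increasing uniform grid", call. = FALSE)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("`concentration` must be finite and non-negative (cm^-3)", call. = FALSE)
  structure(list(sample_times = as.numeric(sample_times),
                 concentration = as.numeric(concentration),
                 dt = stats::median(dt), source = source,
                 counter_flow = counter_flow),
            class = "concentration_trace")
}

#' @export
print.concentration_trace <- function(x, ...) {
  cat(sprintf("Concentration trace (%s): %d samples at %.2g Hz, mean %.0f cm^-3\n",
              x$source, length(x$concentration), 1 / x$dt,
              mean(x$concentration)))
  invisible(x)
}

#' Windowed mean concentration with counting uncertainty
#'
#' Arithmetic mean over a time window, with the Poisson counting standard
#' deviation implied by the counter flow: over a window of length T the
#' counter samples a volume `v = counter_flow * T`, so the SD of the mean is
#' `sqrt(Cbar / v)`.
#'
#' @param trace A [concentration_trace()].
#' @param window Length-2 numeric, `[start, end]` times (s); must lie inside
#'   the trace and contain at least 2 samples.
#' @return List with `mean` (cm^-3), `sd` (cm^-3), `n_samples`, `window`.
#' @export
window_mean <- function(trace, window) {
  stopifnot(inherits(trace, "concentration_trace"))
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("`window` must be [start, end] with end > start", call. = FALSE)
  tt <- trace$sample_times
  if (window[1L] < tt[1L] - trace$dt / 2 || window[2L] > tt[length(tt)] + trace$dt / 2)
    stop("window lies outside the trace", call. = FALSE)
  sel <- tt >= window[1L] & tt <= window[2L]
  if (sum(sel) < 2L) stop("window contains fewer than 2 samples", call. = FALSE)
  m <- mean(trace$concentration[sel])
  span <- window[2L] - window[1L]
  sampled_volume <- trace$counter_flow * span        # cm^3 counted
  list(mean = m, sd = sqrt(max(m, 0) / sampled_volume),
       n_samples = sum(sel), window = window)
}

#' One single-breath measurement record
#'
#' Bundles the windowed mean concentrations, particle, maneuver metrics and
#' instrument passage time needed to evaluate the recovery.
#'
#' @param C_reservoir,C_sample Windowed means from [window_mean()] (lists
#'   with `mean` and `sd`), or bare numbers (SD then taken as 0).
#' @param particle A [particle_spec()].
#' @param metrics A [maneuver_metrics()] (optional but required for
#'   residence-time analyses).
#' @param t_instrument Instrument passage time (s) for the loss correction.
#' @param qc_flags Character vector of QC flags carried into the result.
#' @return An object of class `measurement_record`.
#' @export
measurement_record <- function(C_reservoir, C_sample, particle,
                               metrics = NULL, t_instrument, qc_flags = character()) {
  as_wm <- function(x, nm) {
    if (is.numeric(x) && length(x) == 1L) x <- list(mean = x, sd = 0)
    if (!is.list(x) || is.null(x$mean) || is.null(x$sd))
      stop(sprintf("`%s` must be a window_mean() result or a number", nm),
           call. = FALSE)
    if (x$mean < 0) stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    x
  }
  structure(list(C_reservoir = as_wm(C_reservoir, "C_reservoir"),
                 C_sample = as_wm(C_sample, "C_sample"),
                 particle = as_particle_spec(particle),
                 metrics = metrics, t_instrument = t_instrument,
                 qc_flags = qc_flags),
            class = "measurement_record")
}

#' Loss-corrected particle recovery for one measurement
#'
#' Evaluates `R = (C_sample / C_reservoir) / R_instrument`, the fraction of
#' inhaled particles re-emerging in the analyzed exhaled slice after
#' correcting for diffusional losses in the instrument. Scaling both
#' concentrations by a common factor leaves R unchanged by construction.
#' Counting uncertainty is propagated from both window SDs. An instrument
#' penetration below 0.1 (losses above 90%, as for 22 nm particles at long
#' passage times) sets a `low_confidence` flag; R above 1.2 sets `qc_fail`.
#'
#' @param record A [measurement_record()].
#' @param loss A [loss_model()].
#' @return An object of class `recovery_result`: list with `R`, `R_raw`
#'   (uncorrected ratio), `R_instrument_applied`, `uncertainty` (SD of R) and
#'   `qc_flags`. The identity `R_raw == R * R_instrument_applied` holds
#'   exactly.
#' @examples
#' rec <- measurement_record(4000, 200, particle_spec(100e-9), t_instrument = 2)
#' compute_recovery(rec, identity_loss_model())$R # 0.05
#' @export
compute_recovery <- function(record, loss) {
  stopifnot(inherits(record, "measurement_record"), inherits(loss, "loss_model"))
  Cr <- record$C_reservoir; Cs <- record$C_sample
  if (Cr$mean <= 0)
    stop("zero reservoir concentration: recovery undefined", call. = FALSE)
  r_inst <- penetration(loss, record$particle, record$t_instrument)
  R_raw <- Cs$mean / Cr$mean
  R <- R_raw / r_inst
  rel_sd <- sqrt((Cs$sd / max(Cs$mean, .Machine$double.eps))^2 +
                 (Cr$sd / Cr$mean)^2)
  flags <- record$qc_flags
  if (r_inst < 0.1) flags <- c(flags, "low_confidence")
  if (R > 1.2) flags <- c(flags, "qc_fail")
  structure(list(R = R, R_raw = R_raw, R_instrument_applied = r_inst,
                 uncertainty = R * rel_sd, qc_flags = unique(flags)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Recovery R = %.4f (raw ratio %.4f / R_instrument %.4f), SD %.2g\n",
              x$R, x$R_raw, x$R_instrument_applied, x$uncertainty))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate repeated measurements of one condition
#'
#' Sample mean and SD over repeats of a single (subject, particle size,
#' breath-hold) condition. A repeat SD above 0.011 — the worst repeatability
#' observed with the reference instrument — is flagged.
#'
#' @param R Numeric vector of recoveries (or a list of `recovery_result`s).
#' @param condition Optional condition key; if `R` carries a `condition`
#'   attribute per element, all must match.
#' @param sd_flag_threshold Flag threshold on the repeat SD, default 0.011.
#' @return List with `mean`, `sd`, `n`, `flagged`.
#' @export
aggregate_repeats <- function(R, condition = NULL, sd_flag_threshold = 0.011) {
  if (is.list(R) && all(vapply(R, inherits, logical(1), "recovery_result")))
    R <- vapply(R, `[[`, numeric(1), "R")
  if (!is.numeric(R) || length(R) < 2L)
    stop("need at least 2 repeats", call. = FALSE)
  if (!is.null(condition) && length(unique(condition)) > 1L)
    stop("repeats mix different conditions: ",
         paste(unique(condition), collapse = " vs "), call. = FALSE)
  s <- stats::sd(R)
  list(mean = mean(R), sd = s, n = length(R), flagged = s > sd_flag_threshold)
}

#' Fit the exponential recovery-vs-residence-time curve
#'
#' Least-squares fit of `R(t) = R0 * exp(-t / tau)` to (residence time,
#' recovery) points. By default residuals are taken in linear R space with
#' optional inverse-variance weights from the counting SDs; this matches the
#' detector physics (absolute counting noise) rather than amplifying noise at
#' small R as a log-space fit would. Non-positive R values are excluded with
#' a warning.
#'
#' @param t_res Residence times (s).
#' @param R Recoveries.
#' @param weights Optional weights (e.g. `1 / sd^2`); default unweighted.
#' @return An object of class `recovery_curve`: list with `R0`, `tau` (s),
#'   `fit_covariance`, `n_points`, `residuals`.
#' @examples
#' t <- c(5, 8, 12, 16, 20, 24)
#' fit <- fit_recovery_curve(t, 0.3 * exp(-t / 8))
#' c(fit$R0, fit$tau) # 0.3, 8
#' @export
fit_recovery_curve <- function(t_res, R, weights = NULL) {
  stopifnot(is.numeric(t_res), is.numeric(R), length(t_res) == length(R))
  keep <- R > 0 & is.finite(R) & is.finite(t_res)
  if (any(!keep))
    warning(sprintf("%d non-positive/non-finite recovery value(s) excluded",
                    sum(!keep)), call. = FALSE)
  t_res <- t_res[keep]; R <- R[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(R) < 3L || length(unique(signif(t_res, 10))) < 2L)
    stop("degenerate design: need >= 3 points spanning >= 2 residence times",
         call. = FALSE)
  start_fit <- stats::lm(log(R) ~ t_res)
  start <- list(R0 = exp(unname(stats::coef(start_fit)[1])),
                tau = -1 / unname(stats::coef(start_fit)[2]))
  if (!is.finite(start$tau) || start$tau <= 0) start$tau <- diff(range(t_res))
  dat <- data.frame(t_res = t_res, R = R)
  fit <- if (is.null(weights)) {
    minpack.lm::nlsLM(R ~ R0 * exp(-t_res / tau), data = dat, start = start,
                      lower = c(R0 = 1e-12, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    dat$w <- weights
    minpack.lm::nlsLM(R ~ R0 * exp(-t_res / tau), data = dat, start = start,
                      weights = w, lower = c(R0 = 1e-12, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- stats::coef(fit)
  fitted_R <- est[["R0"]] * exp(-t_res / est[["tau"]])
  structure(list(R0 = est[["R0"]], tau = est[["tau"]],
                 fit_covariance = tryCatch(stats::vcov(fit),
                                           error = function(e) NULL),
                 n_points = length(R),
                 residuals = R - fitted_R,
                 t_res = t_res, R = R),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("Recovery curve: R(t) = %.4g * exp(-t / %.3g s), n = %d\n",
              x$R0, x$tau, x$n_points))
  cat(sprintf("  R(10 s) = %.4g, residual RMS = %.2g\n",
              normalize_to_time(x), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
plot.recovery_curve <- function(x, ...) {
  graphics::plot(x$t_res, x$R, xlab = "residence time (s)", ylab = "recovery R",
                 log = "y", ...)
  tg <- seq(min(x$t_res), max(x$t_res), length.out = 100)
  graphics::lines(tg, x$R0 * exp(-tg / x$tau))
  invisible(x)
}

#' Recovery normalized to a reference residence time
#'
#' Evaluates the fitted curve at `t_ref`, by default 10 s — the reference
#' residence time used to compare subjects on a common footing.
#'
#' @param curve A [fit_recovery_curve()] result.
#' @param t_ref Reference residence time (s), default 10.
#' @return `R0 * exp(-t_ref / tau)`.
#' @export
normalize_to_time <- function(curve, t_ref = 10) {
  stopifnot(inherits(curve, "recovery_curve"), is.numeric(t_ref), t_ref >= 0)
  curve$R0 * exp(-t_ref / curve$tau)
}

#' Reservoir stability QC
#'
#' The recovery is insensitive to the absolute reservoir concentration but
#' requires it to be stable over the measurement. Computes the coefficient of
#' variation and the relative linear drift (fitted slope x span / mean);
#' either exceeding its threshold (default 5%) fails the check.
#'
#' @param trace A reservoir [concentration_trace()].
#' @param cv_threshold,drift_threshold Relative thresholds, default 0.05.
#' @return List with `pass`, `cv`, `drift` (relative, signed).
#' @export
stability_qc <- function(trace, cv_threshold = 0.05, drift_threshold = 0.05) {
  stopifnot(inherits(trace, "concentration_trace"))
  y <- trace$concentration
  m <- mean(y)
  if (m <= 0) return(list(pass = FALSE, cv = Inf, drift = Inf))
  cv <- stats::sd(y) / m
  slope <- unname(stats::coef(stats::lm(y ~ trace$sample_times))[2])
  drift <- slope * diff(range(trace$sample_times)) / m
  list(pass = cv <= cv_threshold && abs(drift) <= drift_threshold,
       cv = cv, drift = drift)
}
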
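# Semi-empirical instrument penetration model: evaluate, calibrate from
# syringe runs, and persist. The model corrects measured recovery for
# diffusional particle losses in the mouthpiece, tubing and valves:
#   R_instrument = A * exp(-b * D * t_instrument)
# with D the slip-corrected diffusion coefficient (m^2/s), t_instrument the
# total passage time through the instrument dead volume (s), and empirical
# constants A (dimensionless) and b (m^-2).

#' Construct an instrument loss model
#'
#' @param A Dimensionless pre-factor, in (0, 1.5].
#' @param b Exponent coefficient (m^-2), > 0.
#' @param fit_covariance Optional 2x2 covariance matrix of (A, b) from
#'   calibration.
#' @param calibration_summary Optional list with fields `n`, `residual_rms`,
#'   `pearson_r` describing the calibration fit.
#' @param conditions [gas_conditions()] at which D is evaluated when the model
#'   is applied; defaults to the 35 degC instrument box.
#' @return An object of class `loss_model`.
#' @examples
#' loss_model(A = 1.00, b = 2.63e7)
#' @export
loss_model <- function(A, b, fit_covariance = NULL, calibration_summary = NULL,
                       conditions = gas_conditions()) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0 || A > 1.5)
    stop("`A` must be in (0, 1.5]", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("`b` must be a positive number (m^-2)", call. = FALSE)
  if (!is.null(fit_covariance)) {
    fit_covariance <- as.matrix(fit_covariance)
    stopifnot(identical(dim(fit_covariance), c(2L, 2L)))
  }
  structure(list(A = A, b = b, fit_covariance = fit_covariance,
                 calibration_summary = calibration_summary,
                 conditions = as_gas_conditions(conditions)),
            class = "loss_model")
}

#' Identity loss model (no instrument losses)
#'
#' Convenience model with penetration 1 at all sizes and passage times;
#' useful for testing that recovery then equals the raw concentration ratio.
#' @return A `loss_model` whose penetration is 1 to double precision.
#' @export
identity_loss_model <- function() {
  loss_model(A = 1, b = .Machine$double.xmin)
}

#' @export
print.loss_model <- function(x, ...) {
  cat(sprintf("Instrument loss model: R_instrument = A exp(-b D t)\n"))
  cat(sprintf("  A = %.4g, b = %.4g m^-2 (D at %.2f K)\n",
              x$A, x$b, x$conditions$temperature))
  s <- x$calibration_summary
  if (!is.null(s))
    cat(sprintf("  calibration: n = %d, residual RMS = %.2e, Pearson r = %.4f\n",
                s$n, s$residual_rms, s$pearson_r))
  invisible(x)
}

#' Predicted instrument penetration
#'
#' Evaluates `A * exp(-b * D * t_instrument)`, where D is computed for the
#' particle at the model's gas conditions. At `t_instrument = 0` this
#' returns A.
#'
#' @param model A [loss_model()].
#' @param particle A [particle_spec()] (or diameter in m).
#' @param t_instrument Passage time through the instrument (s), >= 0;
#'   vector OK.
#' @param conditions Optional override of the conditions at which D is
#'   evaluated; default is the model's own conditions.
#' @return Penetration fraction(s) in (0, A].
#' @examples
#' m <- loss_model(1.00, 2.63e7)
#' penetration(m, particle_spec(100e-9), t_instrument = 2.8)
#' @export
penetration <- function(model, particle, t_instrument, conditions = NULL) {
  stopifnot(inherits(model, "loss_model"))
  if (!is.numeric(t_instrument) || any(!is.finite(t_instrument)) ||
      any(t_instrument < 0))
    stop("`t_instrument` must be non-negative and finite (s)", call. = FALSE)
  if (is.null(conditions)) conditions <- model$conditions
  D <- diffusion_value(particle, conditions)
  model$A * exp(-model$b * D * t_instrument)
}

#' Assemble calibration records
#'
#' One row per simulated-breathing syringe run through the instrument:
#' particle size, mean flows on the inhalation and exhalation legs, the
#' resulting passage time, and the observed penetration. Observed penetration
#' slightly above 1 (counting noise) is tolerated up to 1.1; values above
#' 1.02 are flagged.
#'
#' @param size_nm Particle diameter (nm).
#' @param flow_in_Lps,flow_ex_Lps Mean flows on the two legs (L/s).
#' @param t_instrument_s Passage time (s), > 0.
#' @param R_instrument Observed penetration, in (0, 1.1].
#' @return A `data.frame` of class `calibration_records` with a `flagged`
#'   logical column (penetration > 1.02).
#' @export
calibration_records <- function(size_nm, flow_in_Lps, flow_ex_Lps,
                                t_instrument_s, R_instrument) {
  df <- data.frame(size_nm = size_nm, flow_in_Lps = flow_in_Lps,
                   flow_ex_Lps = flow_ex_Lps, t_instrument_s = t_instrument_s,
                   R_instrument = R_instrument)
  if (any(df$t_instrument_s <= 0))
    stop("passage times must be positive", call. = FALSE)
  if (any(df$R_instrument <= 0))
    stop("observed penetrations must be positive", call. = FALSE)
  if (any(df$R_instrument > 1.1)) {
    warning(sprintf("%d record(s) with penetration > 1.1 rejected (counting drift)",
                    sum(df$R_instrument > 1.1)), call. = FALSE)
    df <- df[df$R_instrument <= 1.1, , drop = FALSE]
  }
  df$flagged <- df$R_instrument > 1.02
  if (any(df$flagged))
    warning(sprintf("%d calibration record(s) with penetration > 1.02 flagged",
                    sum(df$flagged)), call. = FALSE)
  class(df) <- c("calibration_records", "data.frame")
  df
}

#' Fit the instrument loss model to calibration records
#'
#' Nonlinear least squares for (A, b) in
#' `R_instrument = A * exp(-b * D * t_instrument)`, with D evaluated per
#' record at `conditions`. The default fits in linear penetration space
#' (residuals on R itself); `space = "log"` fits `log R` instead, which
#' weights small penetrations more heavily. Starting values come from the
#' log-linear regression, which is also the fallback oracle for
#' rank-deficiency detection: the design must span at least two distinct
#' values of `D * t`.
#'
#' @param records A [calibration_records()] data frame (rejected rows with
#'   penetration > 1.1 must already be absent).
#' @param conditions [gas_conditions()] at which D is evaluated
#'   (default 35 degC box).
#' @param space `"linear"` (default) or `"log"` residual space.
#' @return A [loss_model()] with `fit_covariance` and `calibration_summary`
#'   (n, residual RMS, Pearson correlation between observed and fitted)
#'   populated.
#' @examples
#' m0 <- loss_model(1.00, 2.63e7)
#' rec <- generate_calibration_run(m0, noise_cv = 0, seed = 1)
#' fit <- fit_loss_model(rec)
#' c(fit$A, fit$b)
#' @export
fit_loss_model <- function(records, conditions = gas_conditions(),
                           space = c("linear", "log")) {
  space <- match.arg(space)
  if (!is.data.frame(records) || nrow(records) < 4L)
    stop("need at least 4 calibration records", call. = FALSE)
  req <- c("size_nm", "t_instrument_s", "R_instrument")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (length(unique(records$size_nm)) < 2L)
    stop("degenerate design: need at least 2 particle sizes", call. = FALSE)
  if (length(unique(signif(records$t_instrument_s, 10))) < 2L)
    stop("degenerate design: need at least 2 passage times", call. = FALSE)

  conditions <- as_gas_conditions(conditions)
  D <- vapply(records$size_nm * 1e-9, function(d)
    diffusion_coefficient(particle_spec(d), conditions)$value, numeric(1))
  u <- D * records$t_instrument_s      # m^2: exponent scale per record
  R <- records$R_instrument
  if (diff(range(u)) / max(u) < 1e-9)
    stop("degenerate design: all records share one D * t value; ",
         "A and b are not jointly identifiable", call. = FALSE)

  # log-linear start: log R = log A - b u
  start_fit <- stats::lm(log(R) ~ u)
  start <- list(A = exp(unname(stats::coef(start_fit)[1])),
                b = -unname(stats::coef(start_fit)[2]))
  if (!is.finite(start$b) || start$b <= 0) start$b <- 1 / stats::median(u)
  start$A <- min(max(start$A, 1e-3), 1.5)

  dat <- data.frame(u = u, R = R, logR = log(R))
  fit <- if (space == "linear") {
    minpack.lm::nlsLM(R ~ A * exp(-b * u), data = dat, start = start,
                      lower = c(A = 1e-6, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(logR ~ log(A) - b * u, data = dat, start = start,
                      lower = c(A = 1e-6, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  if (!fit$convInfo$isConv && fit$convInfo$stopCode %in% c(5L, 6L))
    stop("loss-model fit did not converge: ", fit$convInfo$stopMessage,
         call. = FALSE)

  est <- stats::coef(fit)
  fitted_R <- est[["A"]] * exp(-est[["b"]] * u)
  resid <- R - fitted_R
  summ <- list(n = nrow(records),
               residual_rms = sqrt(mean(resid^2)),
               pearson_r = stats::cor(R, fitted_R))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  loss_model(A = est[["A"]], b = est[["b"]], fit_covariance = vc,
             calibration_summary = summ, conditions = conditions)
}

#' Passage time through the instrument dead volume
#'
#' The test aerosol traverses the instrument dead volume twice: once during
#' inhalation (phase II to III) and once during the sampled exhalation
#' (phase IV to V). The passage time is
#' `t = V_dead / Qbar_inhale + V_dead / Qbar_exhale` with phase-mean flows.
#'
#' @param flow_trace A [flow_trace()].
#' @param phases A [maneuver_phases()] for the trace.
#' @param instrument_dead_volume Instrument dead volume (L), > 0. Default
#'   0.3 L, the combined mouthpiece/flow-meter/valve estimate.
#' @return Passage time (s).
#' @examples
#' passage_time_from_flows(0.6, 0.6, 0.3) # 1 s
#' @export
passage_time <- function(flow_trace, phases, instrument_dead_volume = 0.3) {
  stopifnot(inherits(flow_trace, "flow_trace"), inherits(phases, "maneuver_phases"))
  vol <- integrate_volume(flow_trace)
  q_in <- phase_mean_flow(flow_trace, vol, phases$II, phases$III)
  q_ex <- -phase_mean_flow(flow_trace, vol, phases$IV, phases$V)
  passage_time_from_flows(q_in, q_ex, instrument_dead_volume)
}

#' @rdname passage_time
#' @param mean_flow_inhale,mean_flow_exhale Phase-mean flow magnitudes (L/s).
#' @export
passage_time_from_flows <- function(mean_flow_inhale, mean_flow_exhale,
                                    instrument_dead_volume = 0.3) {
  if (!is.numeric(instrument_dead_volume) || instrument_dead_volume <= 0)
    stop("`instrument_dead_volume` must be positive (L)", call. = FALSE)
  if (any(mean_flow_inhale <= 0) || any(mean_flow_exhale <= 0))
    stop("zero or negative phase-mean flow: maneuver invalid for passage time",
         call. = FALSE)
  instrument_dead_volume / mean_flow_inhale +
    instrument_dead_volume / mean_flow_exhale
}

# mean flow between two times, from the cumulative volume series (L/s)
phase_mean_flow <- function(trace, vol, t0, t1) {
  v0 <- stats::approx(trace$sample_times, vol, xout = t0, rule = 2)$y
  v1 <- stats::approx(trace$sample_times, vol, xout = t1, rule = 2)$y
  (v1 - v0) / (t1 - t0)
}

#' Read / write calibration records as CSV
#'
#' Columns: `size_nm, flow_in_Lps, flow_ex_Lps, t_instrument_s, R_instrument`.
#' @param path File path.
#' @return `read_calibration_csv()` returns a [calibration_records()] frame.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  calibration_records(df$size_nm, df$flow_in_Lps, df$flow_ex_Lps,
                      df$t_instrument_s, df$R_instrument)
}

#' @rdname read_calibration_csv
#' @param records A [calibration_records()] frame.
#' @export
write_calibration_csv <- function(records, path) {
  df <- as.data.frame(records)
  df$flagged <- NULL
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist / restore a fitted loss model as JSON
#'
#' @param model A [loss_model()].
#' @param path File path.
#' @return `read_loss_model()` returns the restored [loss_model()].
#' @export
write_loss_model <- function(model, path) {
  stopifnot(inherits(model, "loss_model"))
  obj <- list(model = "A * exp(-b * D * t_instrument)",
              A = model$A, b = model$b,
              covariance = if (!is.null(model$fit_covariance))
                unclass(model$fit_covariance) else NULL,
              calibration_summary = model$calibration_summary,
              conditions = list(temperature_K = model$conditions$temperature,
                                pressure_Pa = model$conditions$pressure),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_loss_model
#' @export
read_loss_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loss_model(A = obj$A, b = obj$b,
             fit_covariance = if (length(obj$covariance))
               matrix(unlist(obj$covariance), 2, 2) else NULL,
             calibration_summary = obj$calibration_summary,
             conditions = gas_conditions(obj$conditions$temperature_K,
                                         obj$conditions$pressure_Pa))
}

# numeric columns to 15 significant digits for lossless text round trip
format_numeric_df <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 15,
                                                  format = "g")
  df
}
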
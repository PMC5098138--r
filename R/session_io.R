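# Session-level plumbing: trace and manifest round-tripping (two-column CSV
# plus JSON sidecar), the end-to-end analysis driver, and file-level entry
# points wrapping it (simulate / calibrate / analyze). A thin command-line
# wrapper over these functions ships in inst/cli/aida.R.

#' Write / read a flow trace (CSV + JSON sidecar)
#'
#' The CSV holds `time_s, flow_Lps` to 15 significant digits; the sidecar
#' `<path>.json` holds sampling rate, units and valve events.
#'
#' @param trace A [flow_trace()].
#' @param path CSV file path.
#' @return `read_flow_trace()` returns the restored [flow_trace()].
#' @export
write_flow_trace <- function(trace, path) {
  stopifnot(inherits(trace, "flow_trace"))
  df <- data.frame(time_s = trace$sample_times, flow_Lps = trace$flow)
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE, quote = FALSE)
  side <- list(sampling_rate_hz = 1 / trace$dt, units = "L/s",
               source = "pneumotachograph",
               valve_events = as.list(trace$valve_events))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_flow_trace
#' @export
read_flow_trace <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- if (length(side$valve_events)) unlist(side$valve_events) else NULL
  flow_trace(df$time_s, df$flow_Lps, valve_events = ev)
}

#' Write / read a concentration trace (CSV + JSON sidecar)
#'
#' @param trace A [concentration_trace()].
#' @param path CSV file path.
#' @return `read_concentration_trace()` returns the restored trace.
#' @export
write_concentration_trace <- function(trace, path) {
  stopifnot(inherits(trace, "concentration_trace"))
  df <- data.frame(time_s = trace$sample_times,
                   concentration_cm3 = trace$concentration)
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE, quote = FALSE)
  side <- list(sampling_rate_hz = 1 / trace$dt, units = "cm^-3",
               source = trace$source, counter_flow_cm3ps = trace$counter_flow)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_concentration_trace
#' @export
read_concentration_trace <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  concentration_trace(df$time_s, df$concentration_cm3, source = side$source,
                      counter_flow = side$counter_flow_cm3ps)
}

#' Write a synthetic session to disk
#'
#' Writes per-measurement flow and concentration traces, a `manifest.json`
#' tying them together, and `ground_truth.json` (kept separate; the analysis
#' path never reads it).
#'
#' @param session A [generate_session()] result.
#' @param dir Output directory (created if missing).
#' @param subject Subject identifier recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir, subject = "S1") {
  stopifnot(inherits(session, "synthetic_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (m in session$measurements) {
    base <- file.path(dir, m$id)
    write_flow_trace(m$flow, paste0(base, "_flow.csv"))
    write_concentration_trace(m$reservoir, paste0(base, "_reservoir.csv"))
    write_concentration_trace(m$sample, paste0(base, "_sample.csv"))
    entries[[m$id]] <- list(
      id = m$id, size_nm = m$size_nm, hold_s = m$hold_s, rep = m$rep,
      flow = paste0(m$id, "_flow.csv"),
      reservoir = paste0(m$id, "_reservoir.csv"),
      sample = paste0(m$id, "_sample.csv"),
      reservoir_window = m$reservoir_window,
      sample_window = m$sample_window)
  }
  manifest <- list(subject = subject, seed = session$seed,
                   measurements = unname(entries))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(session$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session from a manifest
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A list with `measurements` (traces and windows) and `subject`;
#'   structurally compatible with [analyze_session()].
#' @export
read_session <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  measurements <- list()
  for (e in man$measurements) {
    for (f in c("flow", "reservoir", "sample")) {
      p <- file.path(dir, e[[f]])
      if (!file.exists(p))
        stop(sprintf("manifest references missing trace file: %s", p),
             call. = FALSE)
    }
    measurements[[e$id]] <- list(
      id = e$id, size_nm = e$size_nm, hold_s = e$hold_s, rep = e$rep,
      flow = read_flow_trace(file.path(dir, e$flow)),
      reservoir = read_concentration_trace(file.path(dir, e$reservoir)),
      sample = read_concentration_trace(file.path(dir, e$sample)),
      reservoir_window = unlist(e$reservoir_window),
      sample_window = unlist(e$sample_window))
  }
  list(subject = man$subject, seed = man$seed, measurements = measurements)
}

#' Analyze a measurement session
#'
#' Runs the full pipeline on every measurement: phase detection, maneuver
#' metrics, passage time, windowed concentration means, loss-corrected
#' recovery (with QC), per-condition aggregation, and per-size exponential
#' recovery-vs-residence-time fits with 10 s normalization. Measurements
#' failing QC are reported with their flags, never silently dropped.
#'
#' @param session A [generate_session()] result or a [read_session()] list.
#' @param loss A [loss_model()].
#' @param instrument_dead_volume Dead volume (L) for the passage time,
#'   default 0.3.
#' @param t_ref Normalization residence time (s), default 10.
#' @return An object of class `session_analysis`: list with `results` (one
#'   row per measurement), `summary` (one row per size x hold condition),
#'   `curves` (per-size [fit_recovery_curve()] objects) and `normalized`
#'   (per-size R at `t_ref`).
#' @export
analyze_session <- function(session, loss, instrument_dead_volume = 0.3,
                            t_ref = 10) {
  stopifnot(inherits(loss, "loss_model"))
  meas <- session$measurements
  stopifnot(length(meas) >= 1L)
  rows <- vector("list", length(meas))
  for (i in seq_along(meas)) {
    m <- meas[[i]]
    row <- tryCatch({
      phases <- detect_phases(m$flow)
      metrics <- maneuver_metrics(m$flow, phases)
      t_inst <- passage_time(m$flow, phases, instrument_dead_volume)
      wm_res <- window_mean(m$reservoir, m$reservoir_window)
      wm_smp <- window_mean(m$sample, m$sample_window)
      qc <- stability_qc(m$reservoir)
      rec <- measurement_record(wm_res, wm_smp,
                                particle_spec(m$size_nm * 1e-9),
                                metrics = metrics, t_instrument = t_inst,
                                qc_flags = if (qc$pass) character()
                                           else "reservoir_unstable")
      res <- compute_recovery(rec, loss)
      data.frame(id = m$id, size_nm = m$size_nm, hold_s = m$hold_s,
                 rep = m$rep, V_i_L = metrics$V_i,
                 hold_meas_s = metrics$breath_hold_time,
                 t_res_s = metrics$residence_time, t_instrument_s = t_inst,
                 R_raw = res$R_raw, R_instrument = res$R_instrument_applied,
                 R = res$R, sd_R = res$uncertainty,
                 qc = paste(res$qc_flags, collapse = ";"))
    }, aidar_maneuver_error = function(e) {
      data.frame(id = m$id, size_nm = m$size_nm, hold_s = m$hold_s,
                 rep = m$rep, V_i_L = NA_real_, hold_meas_s = NA_real_,
                 t_res_s = NA_real_, t_instrument_s = NA_real_,
                 R_raw = NA_real_, R_instrument = NA_real_, R = NA_real_,
                 sd_R = NA_real_, qc = paste0("rejected: ", conditionMessage(e)))
    })
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)

  ok <- !is.na(results$R)
  summ <- NULL
  if (any(ok)) {
    key <- interaction(results$size_nm[ok], results$hold_s[ok], drop = TRUE)
    summ <- do.call(rbind, lapply(split(results[ok, ], key), function(g) {
      agg <- if (nrow(g) >= 2L) aggregate_repeats(g$R)
             else list(mean = g$R, sd = NA_real_, n = 1L, flagged = FALSE)
      data.frame(size_nm = g$size_nm[1], hold_s = g$hold_s[1],
                 mean_R = agg$mean, sd_R = agg$sd, n = agg$n,
                 sd_flagged = agg$flagged)
    }))
    summ <- summ[order(summ$size_nm, summ$hold_s), ]
    rownames(summ) <- NULL
  }

  curves <- list(); normalized <- list()
  for (size in sort(unique(results$size_nm[ok]))) {
    g <- results[ok & results$size_nm == size, ]
    if (nrow(g) >= 3L && length(unique(signif(g$t_res_s, 10))) >= 2L) {
      cv <- fit_recovery_curve(g$t_res_s, g$R)
      curves[[as.character(size)]] <- cv
      normalized[[as.character(size)]] <- normalize_to_time(cv, t_ref)
    }
  }

  structure(list(results = results, summary = summ, curves = curves,
                 normalized = normalized, t_ref = t_ref,
                 subject = session$subject),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  n_fail <- sum(is.na(x$results$R))
  cat(sprintf("Session analysis: %d measurements (%d rejected)\n",
              nrow(x$results), n_fail))
  for (size in names(x$curves)) {
    cv <- x$curves[[size]]
    cat(sprintf("  %s nm: R0 = %.3f, tau = %.2f s, R(%g s) = %.4f\n",
                size, cv$R0, cv$tau, x$t_ref, x$normalized[[size]]))
  }
  invisible(x)
}

#' Simulate a session to disk
#'
#' File-level wrapper over [generate_session()] + [write_session()]; also
#' persists the generating loss model alongside the traces.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param profile A [subject_profile()].
#' @param ... Passed to [generate_session()].
#' @return The manifest path, invisibly.
#' @export
session_simulate <- function(out_dir, seed = 1, profile = subject_profile(),
                             ...) {
  session <- generate_session(profile, seed = seed, ...)
  path <- write_session(session, out_dir)
  write_loss_model(session$loss, file.path(out_dir, "loss_model.json"))
  invisible(path)
}

#' Calibrate the loss model from a records CSV
#'
#' File-level wrapper over [read_calibration_csv()] + [fit_loss_model()] +
#' [write_loss_model()].
#'
#' @param records_path CSV of calibration records.
#' @param out_path Output JSON path for the fitted model.
#' @param ... Passed to [fit_loss_model()].
#' @return The fitted [loss_model()], invisibly.
#' @export
session_calibrate <- function(records_path, out_path, ...) {
  records <- read_calibration_csv(records_path)
  model <- fit_loss_model(records, ...)
  write_loss_model(model, out_path)
  invisible(model)
}

#' Analyze a session from disk
#'
#' File-level wrapper over [read_session()] + [analyze_session()]: writes
#' `results.csv` (one row per measurement), `summary.csv` (one row per
#' condition) and `curves.json` (per-size fits and normalized recovery).
#' Re-running on unchanged inputs is bit-identical.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param loss_model_path Path to the fitted loss-model JSON.
#' @param out_dir Output directory (created if missing).
#' @param ... Passed to [analyze_session()].
#' @return The [analyze_session()] object, invisibly.
#' @export
session_analyze <- function(manifest_path, loss_model_path, out_dir, ...) {
  session <- read_session(manifest_path)
  loss <- read_loss_model(loss_model_path)
  an <- analyze_session(session, loss, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(format_numeric_df(an$results),
                   file.path(out_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(an$summary))
    utils::write.csv(format_numeric_df(an$summary),
                     file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  curves <- lapply(an$curves, function(cv)
    list(R0 = cv$R0, tau_s = cv$tau, n_points = cv$n_points))
  for (nm in names(curves))
    curves[[nm]]$R_normalized <- an$normalized[[nm]]
  jsonlite::write_json(list(t_ref_s = an$t_ref, curves = curves),
                       file.path(out_dir, "curves.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(an)
}
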
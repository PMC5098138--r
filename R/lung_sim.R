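# Simplified forward single-breath deposition simulator.
#
# The lung is modeled as a symmetric dichotomously branching conducting path
# (Gormley-Kennedy diffusional penetration per generation, both directions)
# feeding a single distal airspace compartment, modeled as a sphere of
# effective radius in which the aerosol resides by pure diffusion for the
# residence time of the maneuver. For particles <= 100 nm diffusion is the
# only deposition mechanism retained; sedimentation and impaction are
# negligible at these sizes.

#' Default conducting-path airway table
#'
#' Symmetric Weibel-type generations 0-13 (trachea to small bronchioles).
#' Generations distal of 13 are subsumed into the spherical airspace
#' compartment, which represents the respiratory region at full inflation.
#' Columns: `generation`, `count`, `length_m`, `diameter_m`.
#'
#' @return A `data.frame` with one row per generation, proximal to distal.
#' @export
default_conducting_path <- function() {
  data.frame(
    generation = 0:13,
    count      = 2^(0:13),
    length_m   = c(0.120, 0.0476, 0.0190, 0.0127, 0.0107, 0.0107, 0.0090,
                   0.0076, 0.0064, 0.0054, 0.0046, 0.0039, 0.0033, 0.0027),
    diameter_m = c(0.0180, 0.0122, 0.0083, 0.0056, 0.0045, 0.0035, 0.0028,
                   0.0023, 0.00186, 0.00154, 0.00130, 0.00109, 0.00095,
                   0.00082)
  )
}

#' Lung geometry for the forward simulator
#'
#' @param conducting_path Airway table as in [default_conducting_path()]:
#'   columns `count`, `length_m` (and optionally `generation`, `diameter_m`),
#'   ordered proximal to distal. Flow divides equally among the tubes of a
#'   generation, so parent flow equals the sum of child flows.
#' @param distal_airspace_radius Effective radius of the distal airspace
#'   compartment (m). Default 3e-4 m (0.3 mm), a typical acinar airspace
#'   scale at full inflation.
#' @param functional_residual_fraction Fraction of residual air mixed into
#'   the sample (default 0: the RV-to-TLC maneuver minimizes mixing).
#' @param dead_space Dead space (L), default 0.3.
#' @return An object of class `lung_geometry`.
#' @export
lung_geometry <- function(conducting_path = default_conducting_path(),
                          distal_airspace_radius = 3e-4,
                          functional_residual_fraction = 0,
                          dead_space = 0.3) {
  stopifnot(is.data.frame(conducting_path),
            all(c("count", "length_m") %in% names(conducting_path)))
  if (any(conducting_path$count <= 0) || any(conducting_path$length_m <= 0))
    stop("airway counts and lengths must be positive", call. = FALSE)
  if (!is.numeric(distal_airspace_radius) || distal_airspace_radius <= 0)
    stop("`distal_airspace_radius` must be positive (m)", call. = FALSE)
  if (functional_residual_fraction < 0 || functional_residual_fraction >= 1)
    stop("`functional_residual_fraction` must be in [0, 1)", call. = FALSE)
  if (dead_space <= 0) stop("`dead_space` must be positive (L)", call. = FALSE)
  structure(list(conducting_path = conducting_path,
                 distal_airspace_radius = distal_airspace_radius,
                 functional_residual_fraction = functional_residual_fraction,
                 dead_space = dead_space),
            class = "lung_geometry")
}

#' @export
print.lung_geometry <- function(x, ...) {
  cat(sprintf("Lung geometry: %d conducting generations, airspace radius %.0f um, dead space %.2f L\n",
              nrow(x$conducting_path), x$distal_airspace_radius * 1e6,
              x$dead_space))
  invisible(x)
}

#' Single-breath scenario for the simulator
#'
#' @param particle A [particle_spec()] (or diameter in m).
#' @param inhale_flow,exhale_flow Mean flows (L/s), within 0.1-12.
#' @param breath_hold Breath-hold duration (s), >= 0.
#' @param inhaled_volume Inhaled volume (L), default 4.5 (a typical vital
#'   capacity).
#' @return An object of class `simulated_breath`.
#' @export
simulated_breath <- function(particle, inhale_flow, exhale_flow, breath_hold,
                             inhaled_volume = 4.5) {
  if (any(c(inhale_flow, exhale_flow) < 0.1) || any(c(inhale_flow, exhale_flow) > 12))
    stop("flows must lie within 0.1-12 L/s", call. = FALSE)
  if (breath_hold < 0) stop("`breath_hold` must be >= 0", call. = FALSE)
  if (inhaled_volume <= 0) stop("`inhaled_volume` must be positive (L)", call. = FALSE)
  structure(list(particle = as_particle_spec(particle),
                 inhale_flow = inhale_flow, exhale_flow = exhale_flow,
                 breath_hold = breath_hold, inhaled_volume = inhaled_volume),
            class = "simulated_breath")
}

#' Simulate single-breath recovery
#'
#' Predicted recovery
#' `R = P_tube(inhale) * f_sphere(t_res) * P_tube(exhale)`, where the tube
#' penetrations multiply Gormley-Kennedy factors over the conducting
#' generations (per-tube flow = total flow / tube count) and the sphere
#' kernel is evaluated over the maneuver residence time — the time from half
#' of the aerosol inhaled to the midpoint of the collected sample, computed
#' for square-wave flows as
#' `t_res = V_i / (2 Q_in) + hold + collector / (2 Q_ex)`.
#'
#' @param geometry A [lung_geometry()].
#' @param breath A [simulated_breath()].
#' @param conditions [gas_conditions()]; default body temperature
#'   (37 degC), where the aerosol spends its residence time.
#' @param collector_volume Collector volume (L) entering the residence-time
#'   definition; default 1.2.
#' @return List with `R_pred`, `residence_time` (s), and the factors
#'   `penetration_inhale`, `penetration_exhale`, `airspace_fraction`.
#' @examples
#' g <- lung_geometry()
#' b <- simulated_breath(particle_spec(100e-9), 1.5, 2, breath_hold = 10)
#' simulate_recovery(g, b)$R_pred
#' @export
simulate_recovery <- function(geometry, breath,
                              conditions = gas_conditions(temperature = 310.15),
                              collector_volume = 1.2) {
  stopifnot(inherits(geometry, "lung_geometry"),
            inherits(breath, "simulated_breath"))
  D <- diffusion_value(breath$particle, conditions)

  p_leg <- function(total_flow_Lps) {
    q_tube <- total_flow_Lps * 1e-3 / geometry$conducting_path$count  # m^3/s
    prod(tube_penetration(D, geometry$conducting_path$length_m, q_tube))
  }
  p_in <- p_leg(breath$inhale_flow)
  p_ex <- p_leg(breath$exhale_flow)

  t_res <- breath$inhaled_volume / (2 * breath$inhale_flow) +
    breath$breath_hold + collector_volume / (2 * breath$exhale_flow)
  f_air <- sphere_remaining_fraction(D, t_res, geometry$distal_airspace_radius)
  mix <- 1 - geometry$functional_residual_fraction

  list(R_pred = p_in * f_air * p_ex * mix,
       residence_time = t_res,
       penetration_inhale = p_in,
       penetration_exhale = p_ex,
       airspace_fraction = f_air)
}

#' Breath hold achieving a target residence time
#'
#' Inverts the square-wave residence-time expression used by
#' [simulate_recovery()], so that flow sweeps can be run at constant
#' residence time.
#'
#' @param target_residence_time Desired residence time (s).
#' @inheritParams simulate_recovery
#' @param inhale_flow,exhale_flow,inhaled_volume As in [simulated_breath()].
#' @return Breath-hold duration (s); error if negative.
#' @export
breath_hold_for_residence_time <- function(target_residence_time, inhale_flow,
                                           exhale_flow, inhaled_volume = 4.5,
                                           collector_volume = 1.2) {
  hold <- target_residence_time - inhaled_volume / (2 * inhale_flow) -
    collector_volume / (2 * exhale_flow)
  if (hold < 0)
    stop("target residence time shorter than the transit times themselves",
         call. = FALSE)
  hold
}

#' Effective airspace radius reproducing a target recovery
#'
#' Inverts the sphere kernel: finds the radius at which
#' `f_sphere(D, t, r)` equals `target_fraction`. Useful for building
#' synthetic cohorts spanning a prescribed recovery range.
#'
#' @param target_fraction Target remaining fraction in (0, 1).
#' @param particle A [particle_spec()] (or diameter in m).
#' @param t Residence time (s).
#' @param conditions [gas_conditions()], default body temperature.
#' @return Radius (m).
#' @export
airspace_radius_for_fraction <- function(target_fraction, particle, t,
                                         conditions = gas_conditions(temperature = 310.15)) {
  stopifnot(target_fraction > 0, target_fraction < 1, t > 0)
  D <- diffusion_value(particle, conditions)
  f <- function(r) sphere_remaining_fraction(D, t, r) - target_fraction
  stats::uniroot(f, lower = 1e-6, upper = 1e-1, tol = 1e-12)$root
}

#' Cohort predictions over geometries and breath conditions
#'
#' One deterministic prediction per geometry x condition, reproducing the
#' layout used to compare subjects at a common residence time.
#'
#' @param geometries A list of [lung_geometry()] objects (one per subject).
#' @param conditions_grid A `data.frame` with columns `size_nm` and `hold_s`.
#' @param inhale_flow,exhale_flow Mean flows (L/s) applied to every breath.
#' @param inhaled_volume Inhaled volume (L).
#' @param gas [gas_conditions()], default body temperature.
#' @param collector_volume Collector volume (L).
#' @return A `data.frame` with columns `subject`, `size_nm`, `hold_s`,
#'   `t_res_s`, `R_pred`.
#' @export
cohort_predictions <- function(geometries, conditions_grid,
                               inhale_flow = 1.5, exhale_flow = 2,
                               inhaled_volume = 4.5,
                               gas = gas_conditions(temperature = 310.15),
                               collector_volume = 1.2) {
  stopifnot(length(geometries) >= 1L, is.data.frame(conditions_grid),
            all(c("size_nm", "hold_s") %in% names(conditions_grid)))
  out <- list()
  for (s in seq_along(geometries)) {
    for (i in seq_len(nrow(conditions_grid))) {
      br <- simulated_breath(particle_spec(conditions_grid$size_nm[i] * 1e-9),
                             inhale_flow, exhale_flow,
                             conditions_grid$hold_s[i], inhaled_volume)
      sim <- simulate_recovery(geometries[[s]], br, gas, collector_volume)
      out[[length(out) + 1L]] <- data.frame(
        subject = s, size_nm = conditions_grid$size_nm[i],
        hold_s = conditions_grid$hold_s[i],
        t_res_s = sim$residence_time, R_pred = sim$R_pred)
    }
  }
  do.call(rbind, out)
}
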
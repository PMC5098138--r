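# Aerosol transport physics: gas properties, slip-corrected Stokes-Einstein
# diffusion, and diffusional deposition kernels (sphere, laminar tube).

#' @keywords internal
.const <- list(
  boltzmann    = 1.380649e-23,  # J/K
  T_ref        = 296.15,        # K (23 C) reference for viscosity / mean free path
  P_ref        = 101325,        # Pa
  viscosity_ref = 1.83245e-5,   # Pa s, air at 23 C
  mfp_ref      = 67.3e-9,       # m, air at 23 C, 101.325 kPa
  sutherland   = 110.4          # K, Sutherland constant for air
)

#' Gas conditions
#'
#' Container for the carrier-gas state used throughout the deposition physics.
#' Dynamic viscosity and mean free path are derived from temperature and
#' pressure by Sutherland-type scaling from reference values at 23 degC and
#' 101.325 kPa. The default corresponds to the instrument's heated box
#' (35 degC, 1 atm); distal lung air is better represented by body
#' temperature, `gas_conditions(temperature = 310.15)`.
#'
#' @param temperature Absolute temperature (K). Default 308.15 K (35 degC).
#' @param pressure Absolute pressure (Pa). Default 101325 Pa.
#' @return An object of class `gas_conditions` with fields `temperature`,
#'   `pressure`, `dynamic_viscosity` (Pa s) and `mean_free_path` (m).
#' @examples
#' gas_conditions()                      # instrument box, 35 degC
#' gas_conditions(temperature = 310.15)  # body temperature
#' @export
gas_conditions <- function(temperature = 308.15, pressure = 101325) {
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) ||
      temperature <= 0)
    stop("`temperature` must be a single positive number (K)", call. = FALSE)
  if (!is.numeric(pressure) || length(pressure) != 1L || !is.finite(pressure) ||
      pressure <= 0)
    stop("`pressure` must be a single positive number (Pa)", call. = FALSE)
  obj <- list(
    temperature       = temperature,
    pressure          = pressure,
    dynamic_viscosity = air_viscosity(temperature),
    mean_free_path    = NA_real_
  )
  class(obj) <- "gas_conditions"
  obj$mean_free_path <- mean_free_path(obj)
  obj
}

#' @export
print.gas_conditions <- function(x, ...) {
  cat(sprintf("Gas conditions: T = %.2f K (%.1f degC), P = %.0f Pa\n",
              x$temperature, x$temperature - 273.15, x$pressure))
  cat(sprintf("  viscosity = %.4e Pa s, mean free path = %.2f nm\n",
              x$dynamic_viscosity, x$mean_free_path * 1e9))
  invisible(x)
}

#' Dynamic viscosity of air
#'
#' Sutherland's law, anchored at 1.83245e-5 Pa s at 23 degC.
#'
#' @param temperature Absolute temperature (K).
#' @return Dynamic viscosity (Pa s).
#' @export
air_viscosity <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  S <- .const$sutherland
  .const$viscosity_ref * (temperature / .const$T_ref)^1.5 *
    (.const$T_ref + S) / (temperature + S)
}

#' Mean free path of air molecules
#'
#' Scaled from the reference value 67.3 nm at 23 degC, 101.325 kPa by the
#' standard temperature/pressure correction (inverse-pressure, Sutherland
#' temperature factor).
#'
#' @param conditions A [gas_conditions()] object.
#' @return Mean free path (m).
#' @examples
#' mean_free_path(gas_conditions(296.15)) # 6.73e-8 m by construction
#' @export
mean_free_path <- function(conditions) {
  conditions <- as_gas_conditions(conditions)
  S <- .const$sutherland
  .const$mfp_ref * (.const$P_ref / conditions$pressure) *
    (conditions$temperature / .const$T_ref) *
    (1 + S / .const$T_ref) / (1 + S / conditions$temperature)
}

as_gas_conditions <- function(x) {
  if (inherits(x, "gas_conditions")) return(x)
  stop("expected a `gas_conditions` object; see gas_conditions()", call. = FALSE)
}

#' Particle specification
#'
#' Describes the monodisperse test aerosol: spherical, hydrophobic particles
#' (polystyrene latex in the reference instrument) carrying a single positive
#' charge after mobility selection. Charge is recorded for provenance only;
#' it does not enter the transport model.
#'
#' @param diameter Particle diameter (m). Must lie in the diffusion-dominated
#'   regime, 1 nm to 1 um.
#' @param nominal_label Optional label, e.g. `"50 nm"`. Defaults to the
#'   diameter printed in nm.
#' @param charge_state Integer number of elementary charges (default +1).
#' @return An object of class `particle_spec`.
#' @examples
#' particle_spec(50e-9)
#' @export
particle_spec <- function(diameter, nominal_label = NULL, charge_state = 1L) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter))
    stop("`diameter` must be a single finite number (m)", call. = FALSE)
  if (diameter < 1e-9 || diameter > 1e-6)
    stop("`diameter` must lie in [1 nm, 1 um], the diffusion-dominated regime",
         call. = FALSE)
  if (is.null(nominal_label))
    nominal_label <- sprintf("%g nm", diameter * 1e9)
  structure(list(diameter = diameter, nominal_label = nominal_label,
                 charge_state = as.integer(charge_state)),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("Particle: %s (d = %.3g nm, charge %+d e)\n",
              x$nominal_label, x$diameter * 1e9, x$charge_state))
  invisible(x)
}

as_particle_spec <- function(x) {
  if (inherits(x, "particle_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(particle_spec(x))
  stop("expected a `particle_spec` object or a diameter in m", call. = FALSE)
}

#' Cunningham slip correction factor
#'
#' Davies parameterization
#' `Cc = 1 + Kn * (1.257 + 0.400 * exp(-1.100 / Kn))` with Knudsen number
#' `Kn = 2 * lambda / d`. Always >= 1; tends to 1 in the continuum limit and
#' grows monotonically with Kn, which dominates transport of sub-100 nm
#' particles.
#'
#' @param diameter Particle diameter (m); may be a vector.
#' @param conditions A [gas_conditions()] object.
#' @return Dimensionless slip factor, same length as `diameter`.
#' @examples
#' cunningham_slip_factor(100e-9, gas_conditions()) # about 3.0 at 35 degC
#' @export
cunningham_slip_factor <- function(diameter, conditions = gas_conditions()) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0))
    stop("`diameter` must be positive and finite (m)", call. = FALSE)
  conditions <- as_gas_conditions(conditions)
  kn <- 2 * conditions$mean_free_path / diameter
  1 + kn * (1.257 + 0.400 * exp(-1.100 / kn))
}

#' Slip-corrected Brownian diffusion coefficient
#'
#' Stokes-Einstein with Cunningham slip:
#' `D = kB * T * Cc / (3 * pi * mu * d)`. Strictly decreasing in diameter
#' over the supported range, which is what makes particle size a depth probe
#' for diffusional deposition.
#'
#' @param particle A [particle_spec()] object (or a diameter in m).
#' @param conditions A [gas_conditions()] object.
#' @return An object of class `diffusion_coefficient` with fields `value`
#'   (m^2/s), `particle` and `conditions`.
#' @examples
#' diffusion_coefficient(particle_spec(100e-9))$value # about 7.3e-10 m^2/s
#' @export
diffusion_coefficient <- function(particle, conditions = gas_conditions()) {
  particle <- as_particle_spec(particle)
  conditions <- as_gas_conditions(conditions)
  cc <- cunningham_slip_factor(particle$diameter, conditions)
  value <- .const$boltzmann * conditions$temperature * cc /
    (3 * pi * conditions$dynamic_viscosity * particle$diameter)
  structure(list(value = value, particle = particle, conditions = conditions),
            class = "diffusion_coefficient")
}

#' @export
print.diffusion_coefficient <- function(x, ...) {
  cat(sprintf("D = %.4e m^2/s for %s at %.2f K\n",
              x$value, x$particle$nominal_label, x$conditions$temperature))
  invisible(x)
}

# Numeric D, accepting a diffusion_coefficient, particle_spec, or plain number.
diffusion_value <- function(particle, conditions = gas_conditions()) {
  if (inherits(particle, "diffusion_coefficient")) return(particle$value)
  if (is.numeric(particle) && length(particle) == 1L && particle < 1e-3 &&
      particle > 1e-12 && particle < 1e-6) {
    # a bare number in (1e-12, 1e-6) is ambiguous; treat as diameter (m)
    return(diffusion_coefficient(particle_spec(particle), conditions)$value)
  }
  diffusion_coefficient(as_particle_spec(particle), conditions)$value
}

#' Fraction of particles remaining airborne in a spherical cavity
#'
#' Eigenfunction series for pure diffusion to a perfectly absorbing spherical
#' wall, starting from a uniform concentration:
#' `f(t) = (6/pi^2) * sum_n n^-2 * exp(-n^2 pi^2 D t / r^2)`.
#' This kernel is the reason loss-corrected recovery declines (asymptotically)
#' exponentially with residence time: for `D t / r^2` beyond about 0.05 the
#' n = 1 mode dominates and `log f` is linear in `t` with decay time
#' `r^2 / (pi^2 D)`.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param t Residence time (s); `t = 0` allowed. May be a vector.
#' @param radius Sphere radius (m).
#' @param tol Series truncation: terms are added until the next term is below
#'   `tol` (default 1e-12) or 1e4 terms.
#' @return Remaining airborne fraction in (0, 1], same length as `t`.
#' @examples
#' sphere_remaining_fraction(1, 0.1, 1) # Dt/r^2 = 0.1 -> about 0.2295
#' @export
sphere_remaining_fraction <- function(D, t, radius, tol = 1e-12) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive number (m^2/s)", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("`radius` must be a single positive number (m)", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative and finite (s)", call. = FALSE)
  x <- D * t / radius^2          # dimensionless diffusion time
  vapply(x, .sphere_series, numeric(1), tol = tol)
}

.sphere_series <- function(x, tol = 1e-12) {
  if (x == 0) return(1)
  total <- 0
  for (n in seq_len(10000L)) {
    term <- exp(-n^2 * pi^2 * x) / n^2
    total <- total + term
    if (term < tol) break
  }
  max(6 / pi^2 * total, .Machine$double.xmin)
}

#' Diffusional penetration through a laminar tube
#'
#' Gormley-Kennedy solution for fully developed laminar flow with a perfectly
#' absorbing wall, parameterized by the deposition parameter
#' `mu = pi * D * L / Q`. Uses the four-term eigenvalue series for
#' `mu >= 0.02` and the short-tube expansion below; the two branches agree at
#' the switch point to within 2e-4.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param length Tube length (m).
#' @param flow Volumetric flow through the tube (m^3/s).
#' @return Penetration fraction in (0, 1].
#' @examples
#' tube_penetration(2.5e-9, 1, 1.667e-5) # CPC sampling line, 50 nm
#' @export
tube_penetration <- function(D, length, flow) {
  if (!is.numeric(D) || any(D <= 0) || any(!is.finite(D)))
    stop("`D` must be positive (m^2/s)", call. = FALSE)
  if (!is.numeric(length) || any(length <= 0) || any(!is.finite(length)))
    stop("`length` must be positive (m)", call. = FALSE)
  if (!is.numeric(flow) || any(flow <= 0) || any(!is.finite(flow)))
    stop("`flow` must be positive (m^3/s)", call. = FALSE)
  mu <- pi * D * length / flow
  gormley_kennedy(mu)
}

#' Gormley-Kennedy penetration as a function of the deposition parameter
#'
#' @param mu Deposition parameter `pi * D * L / Q` (dimensionless), vector OK.
#' @return Penetration fraction in (0, 1].
#' @export
gormley_kennedy <- function(mu) {
  stopifnot(is.numeric(mu), all(is.finite(mu)), all(mu >= 0))
  p <- ifelse(mu < 0.02,
    1 - 2.5638 * mu^(2 / 3) + 1.2 * mu + 0.17676 * mu^(4 / 3),
    0.81905 * exp(-3.6568 * mu) + 0.09753 * exp(-22.305 * mu) +
      0.0325 * exp(-56.961 * mu) + 0.01544 * exp(-107.62 * mu))
  pmin(pmax(p, .Machine$double.xmin), 1)
}
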
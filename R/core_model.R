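#' thermoskin: hyperbolic bioheat and thermoelastic vibration of laser-heated skin
#'
#' Couples the two-dimensional Cattaneo-Vernotte (hyperbolic) bioheat equation
#' with the axisymmetric thermoelastic displacement equations of a homogeneous
#' single-layer skin model, reduced to a three degree-of-freedom system by a
#' Galerkin projection.  See `vignette("thermoskin-methods")` for the model,
#' its assumptions and the numerical choices.
#'
#' @keywords internal
#' @aliases thermoskin-package
#' @importFrom stats integrate spline complete.cases
#' @importFrom utils head tail write.table
#' @importFrom deSolve ode
#' @importFrom yaml read_yaml write_yaml
"_PACKAGE"

CELSIUS_OFFSET <- 273.15

## ---- parameter containers -------------------------------------------------

#' Tissue parameter set
#'
#' Elastic, thermal, damping and thermal-relaxation properties of the skin,
#' treated as a single homogeneous linear layer.  Defaults are the bundled
#' skin preset (density 1000 kg/m3, specific heat 4187 J/(kg K), conductivity
#' 0.628 W/(m K), E = 100 MPa, nu = 0.4, alpha_T = 1e-4 1/K, relaxation time
#' 3 s, reference temperature 37 C).
#'
#' @param density tissue density rho (kg/m3)
#' @param specific_heat specific heat c (J/(kg K))
#' @param conductivity thermal conductivity k (W/(m K))
#' @param youngs_modulus elastic modulus E (Pa)
#' @param poisson Poisson ratio nu, strictly inside (0, 0.5); nu -> 0.5 is the
#'   incompressible limit where the Lame constant diverges
#' @param thermal_expansion linear thermal expansion alpha_T (1/K)
#' @param damping structural damping coefficient (kg/(m3 s)); no published
#'   value, defaults to 0
#' @param relaxation_time Cattaneo-Vernotte relaxation time tau (s); must be
#'   positive for the hyperbolic model
#' @param reference_temperature_C reference (body) temperature (degrees C);
#'   stored internally in kelvin
#' @return object of class `tissue_model`
#' @export
tissue_model <- function(density = 1000, specific_heat = 4187,
                         conductivity = 0.628, youngs_modulus = 100e6,
                         poisson = 0.4, thermal_expansion = 1e-4,
                         damping = 0, relaxation_time = 3,
                         reference_temperature_C = 37) {
  stopifnot(is.numeric(density), is.numeric(specific_heat))
  if (density <= 0 || specific_heat <= 0 || conductivity <= 0 ||
      youngs_modulus <= 0) {
    stop("density, specific heat, conductivity and elastic modulus must be positive")
  }
  if (poisson <= 0 || poisson >= 0.5) {
    stop("Poisson ratio must lie strictly in (0, 0.5); ",
         "nu = 0.5 is incompressible (Lame constant diverges)")
  }
  if (thermal_expansion < 0) stop("thermal expansion must be >= 0")
  if (damping < 0) stop("damping coefficient must be >= 0")
  if (relaxation_time <= 0) {
    stop("relaxation time tau must be > 0 for the hyperbolic model; ",
         "the tau -> 0 (Pennes) limit is available through the finite-difference ",
         "oracle's parabolic mode")
  }
  structure(list(
    density = density, specific_heat = specific_heat,
    conductivity = conductivity, youngs_modulus = youngs_modulus,
    poisson = poisson, thermal_expansion = thermal_expansion,
    damping = damping, relaxation_time = relaxation_time,
    T0 = reference_temperature_C + CELSIUS_OFFSET
  ), class = "tissue_model")
}

#' Blood parameter set
#'
#' Perfusion acts as a distributed heat sink rho_b c_b G_b (T_b - T).
#'
#' @param density blood density (kg/m3)
#' @param specific_heat blood specific heat (J/(kg K))
#' @param perfusion_rate volumetric blood perfusion rate G_b (1/s)
#' @param artery_temperature_C arterial blood temperature (degrees C); `NULL`
#'   (the default) means equal to the tissue reference temperature, i.e. the
#'   perfusion sink relaxes the tissue back to body temperature
#' @return object of class `blood_model`
#' @export
blood_model <- function(density = 1060, specific_heat = 3860,
                        perfusion_rate = 1.87e-3,
                        artery_temperature_C = NULL) {
  if (density <= 0 || specific_heat <= 0) {
    stop("blood density and specific heat must be positive")
  }
  if (perfusion_rate < 0) stop("perfusion rate must be >= 0")
  structure(list(
    density = density, specific_heat = specific_heat,
    perfusion_rate = perfusion_rate,
    Tb = if (is.null(artery_temperature_C)) NULL
         else artery_temperature_C + CELSIUS_OFFSET
  ), class = "blood_model")
}

## ---- derived constants ----------------------------------------------------

#' Lame constants and thermal modulus
#'
#' lambda = E nu / ((1+nu)(1-2nu)), mu = E / (2(1+nu)), and the thermal-stress
#' modulus B = E alpha_T / (1-2nu) that multiplies the temperature term of the
#' constitutive law.
#'
#' @param tissue a [tissue_model()]
#' @return list with `lambda`, `mu`, `thermal_modulus` (all Pa, Pa, Pa/K)
#' @export
elastic_constants <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  E <- tissue$youngs_modulus
  nu <- tissue$poisson
  list(
    lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
    mu = E / (2 * (1 + nu)),
    thermal_modulus = E * tissue$thermal_expansion / (1 - 2 * nu)
  )
}

#' Thermal diffusivity, optical penetration depth and characteristic time
#'
#' alpha = k/(rho c); delta = 1/sqrt(3 mu_a (mu_a + mu_s (1-g))); t* = delta^2/alpha.
#' delta is the length scale of the nondimensionalization and t* its time scale.
#'
#' @param tissue a [tissue_model()]
#' @param optics a [laser_optics()]
#' @return list with `alpha` (m2/s), `delta` (m), `tstar` (s)
#' @export
transport_scales <- function(tissue, optics) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(optics, "laser_optics"))
  mu_a <- optics$absorption
  mu_s_red <- optics$scattering * (1 - optics$anisotropy)
  if (mu_a <= 0) stop("absorption coefficient mu_a must be > 0")
  if (mu_a + mu_s_red <= 0) stop("mu_a + mu_s (1-g) must be > 0")
  alpha <- tissue$conductivity / (tissue$density * tissue$specific_heat)
  delta <- 1 / sqrt(3 * mu_a * (mu_a + mu_s_red))
  list(alpha = alpha, delta = delta, tstar = delta^2 / alpha)
}

#' Nondimensional coefficient groups
#'
#' Computes the seven mechanical groups M1..M7 and seven thermal groups N1..N7
#' of the nondimensional coupled system, together with the derived scales.
#' `rho4` is the perfusion group multiplying (theta - theta_b) in the heat
#' equation and equals `N4`.  The returned list is the single immutable
#' parameter bundle consumed by the assembler, the integrator and the
#' finite-difference solver.
#'
#' @param tissue a [tissue_model()]
#' @param blood a [blood_model()]
#' @param optics a [laser_optics()]
#' @return object of class `nondim_groups`
#' @export
nondim_groups <- function(tissue, blood, optics) {
  stopifnot(inherits(blood, "blood_model"))
  el <- elastic_constants(tissue)
  sc <- transport_scales(tissue, optics)
  alpha <- sc$alpha; delta <- sc$delta; tstar <- sc$tstar
  rho <- tissue$density; cc <- tissue$specific_heat
  tau <- tissue$relaxation_time
  T0 <- tissue$T0
  B <- el$thermal_modulus
  rc <- rho * cc
  perf <- blood$density * blood$specific_heat * blood$perfusion_rate
  Tb <- if (is.null(blood$Tb)) T0 else blood$Tb

  g <- list(
    M1 = tissue$damping * delta^2 / (rho * alpha),
    M2 = (el$lambda + 2 * el$mu) * delta^2 / (rho * alpha^2),
    M3 = el$mu * delta^2 / (rho * alpha^2),
    M4 = (el$lambda + el$mu) * delta^2 / (rho * alpha^2),
    M5 = B * T0 * delta^2 / (rho * alpha^2),
    M6 = (el$lambda + 2 * el$mu) / el$lambda,
    M7 = B * T0 / el$lambda,
    N1 = B / rc,
    N2 = tstar / tau + perf * tstar / rc,
    N3 = B * tstar / (rc * tau),
    N4 = perf * tstar^2 / (rc * tau),
    N5 = tstar^2 / (rc * tau * T0),
    # coefficient of dQ/dt-hat; equals the printed t*^2/(rho c T0) group
    # divided by t* because the source derivative is taken in nondim time
    N6 = tstar / (rc * T0),
    N7 = delta^2 / (tau * alpha),
    alpha = alpha, delta = delta, tstar = tstar,
    tau = tau, T0 = T0,
    theta_b = (Tb - T0) / T0,
    lambda = el$lambda, mu = el$mu, thermal_modulus = B
  )
  g$rho4 <- g$N4
  structure(g, class = "nondim_groups")
}
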
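# Fur-layer insulation: conduction through an air/hair matrix plus a
# radiation-conduction term, with fractional coverage for sparse pelts and
# wind disruption of the trapped-air layer.

#' Fur-layer thermal resistance and effective conductivity
#'
#' The layer conducts through still air and across hair fibres in
#' parallel; radiative transfer within the fur adds a conduction-like term
#' `16 sigma T^3 / (3 beta)` with extinction `beta = chi * n * d`, scaled
#' by the squared coverage so that a vanishing pelt reverts to pure air.
#' Wind augments the conductive term by `1 + c_w * u^0.8` (penetration and
#' disturbance of the trapped air).  Sparse pelts additionally leave a
#' fraction `1 - coverage` of the skin exchanging directly with the
#' environment; that pathway lives in the heat-balance network, not here.
#'
#' @param fur_density_cm2 Hairs per cm^2 (0 allowed).
#' @param hair_diameter_um Hair diameter, micrometres.
#' @param fur_depth_mm Fur layer depth, mm.
#' @param wind Wind speed at the animal, m/s.
#' @param t_mean_c Mean layer temperature for the radiative term, deg C.
#' @param config List from [endotherm_config()].
#' @return List: `k_effective` (W/m K), `resistance` (K m^2/W, = depth /
#'   k_effective), `optical_depth`, `coverage` (fraction of surface
#'   behaving as fur-covered), `k_conduction`, `k_radiative`.
#' @export
fur_layer_resistance <- function(fur_density_cm2, hair_diameter_um,
                                 fur_depth_mm, wind = 0.1, t_mean_c = 15,
                                 config = endotherm_config()) {
  if (fur_density_cm2 < 0 || hair_diameter_um <= 0 || fur_depth_mm < 0)
    stop("fur geometry must be non-negative", call. = FALSE)
  n_m2 <- fur_density_cm2 * 1e4
  d_m <- hair_diameter_um * 1e-6
  depth_m <- fur_depth_mm / 1000
  f_hair <- n_m2 * pi * d_m^2 / 4          # hair volume fraction
  k_air_v <- air_conductivity(t_mean_c)
  # deeper pile is disturbed more by wind (less stable trapped-air layer)
  depth_fac <- (max(fur_depth_mm, 1e-3) / 10)^config$wind_penetration_depth_exp
  wind_factor <- 1 + config$wind_penetration * max(0, wind)^0.8 * depth_fac
  k_cond <- (k_air_v * (1 - f_hair) + config$k_hair_cross * f_hair) *
    wind_factor
  beta <- config$chi_extinction * n_m2 * d_m  # extinction, 1/m
  od <- beta * depth_m
  coverage <- 1 - exp(-od)
  tk <- c_to_k(t_mean_c)
  k_rad <- if (beta > 0) 16 * SIGMA_SB * tk^3 / (3 * beta) * coverage^2 else 0
  k_eff <- k_cond + k_rad
  resistance <- if (depth_m > 0) depth_m / k_eff else 0
  list(k_effective = k_eff, resistance = resistance, optical_depth = od,
       coverage = coverage, k_conduction = k_cond, k_radiative = k_rad)
}

#' Respiratory evaporative heat loss
#'
#' Ventilation follows oxygen demand (20.1 J per mL O2, 20.95% O2 in air,
#' extraction efficiency as given); expired air is saturated at a
#' temperature set by nasal countercurrent recovery,
#' `t_exhale = t_air + r * (core_temp - t_air)`.  Latent heat 2.4 kJ/g.
#' Condensation gains are not allowed (loss floor 0).
#'
#' @param q_gen Metabolic rate, W.
#' @param t_air Inspired air temperature, deg C.
#' @param rh Inspired relative humidity, percent.
#' @param o2_extraction Oxygen extraction efficiency, percent.
#' @param core_temp Core temperature, deg C.
#' @param exhale_recovery Countercurrent recovery coefficient r in [0, 1]
#'   (0 = exhale at air temperature, 1 = at core temperature).
#' @return Evaporative heat loss, W.
#' @export
respiratory_evaporation <- function(q_gen, t_air, rh, o2_extraction,
                                    core_temp = 40.1,
                                    exhale_recovery = 0.05) {
  if (rh < 0 || rh > 100) stop("rh must be in [0, 100]", call. = FALSE)
  if (o2_extraction <= 0 || o2_extraction > 100)
    stop("o2_extraction must be in (0, 100]", call. = FALSE)
  stopifnot(q_gen >= 0)
  v_o2 <- q_gen / ENERGY_PER_ML_O2 * 1e-6          # m^3 O2 / s
  vent <- v_o2 / (O2_FRACTION_AIR * o2_extraction / 100)  # m^3 air / s
  t_ex <- t_air + exhale_recovery * (core_temp - t_air)
  d_rho <- vapour_density(t_ex, 100) - vapour_density(t_air, rh)
  max(0, vent * d_rho * LATENT_HEAT_VAP)
}
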
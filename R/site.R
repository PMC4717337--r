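# Site and daily-weather containers with validation, plus the baseline
# Glacier National Park (GNP) conventions used throughout.

#' Define a study site
#'
#' Geometry and substrate properties of a talus site.  Defaults describe
#' the standard field-simulation site: an eastern aspect, a 15 degree
#' slope, GNP latitude, with a solid-substrate column standing in for the
#' porous talus (the equivalent solid depths 0.15 and 0.20 m are per-site
#' calibrations of rock size).
#'
#' @param latitude Degrees north.
#' @param elevation Metres above sea level.
#' @param slope Slope angle, degrees (0-90).
#' @param aspect Aspect, degrees clockwise from north (0-360).
#' @param substrate_conductivity W/(m K) of the solid substrate.
#' @param substrate_density kg/m^3.
#' @param substrate_specific_heat J/(kg K); field range 700-1000.
#' @param substrate_reflectivity Shortwave reflectivity (fraction).
#' @param refuge_depths Below-surface refuge depths, m.
#' @param animal_height Height of the animal's midpoint above ground, m.
#' @param roughness_length Aerodynamic roughness of the talus surface, m.
#' @param reference_height Height of the reference weather (wind and air
#'   temperature) above ground, m.
#' @return An object of class `pika_site` (a named list).
#' @export
pika_site <- function(latitude = 48.7, elevation = 1500, slope = 15,
                      aspect = 90, substrate_conductivity = 2.5,
                      substrate_density = 2650,
                      substrate_specific_heat = 850,
                      substrate_reflectivity = 0.25,
                      refuge_depths = c(0.15, 0.20),
                      animal_height = 0.09,
                      roughness_length = 0.01,
                      reference_height = 2.0) {
  if (abs(latitude) > 90) stop("latitude must be in [-90, 90]", call. = FALSE)
  if (slope < 0 || slope >= 90) stop("slope must be in [0, 90)", call. = FALSE)
  if (aspect < 0 || aspect >= 360) stop("aspect must be in [0, 360)", call. = FALSE)
  stopifnot(substrate_conductivity > 0, substrate_density > 0,
            substrate_specific_heat > 0, animal_height > 0,
            roughness_length > 0, reference_height > animal_height)
  if (substrate_reflectivity < 0 || substrate_reflectivity > 1)
    stop("substrate_reflectivity must be a fraction in [0, 1]", call. = FALSE)
  structure(list(
    latitude = latitude, elevation = elevation, slope = slope,
    aspect = aspect, substrate_conductivity = substrate_conductivity,
    substrate_density = substrate_density,
    substrate_specific_heat = substrate_specific_heat,
    substrate_reflectivity = substrate_reflectivity,
    refuge_depths = refuge_depths, animal_height = animal_height,
    roughness_length = roughness_length,
    reference_height = reference_height
  ), class = "pika_site")
}

#' Daily weather for the representative day
#'
#' @param t_min,t_max Daily extremes (deg C) at `reference_elevation`.
#' @param wind_min,wind_max Diurnal wind range at pika height (m/s);
#'   the field standard varies 0.1-4.0 m/s.
#' @param cloud_cover Percent (0-100).
#' @param rh Relative humidity, percent.
#' @param reference_elevation Elevation (m) the extremes refer to.
#' @return Object of class `daily_weather`.
#' @export
daily_weather <- function(t_min, t_max, wind_min = 0.1, wind_max = 4.0,
                          cloud_cover = 10, rh = 50,
                          reference_elevation = 1500) {
  assert_finite(c(t_min, t_max))
  if (t_min > t_max) stop("t_min must be <= t_max", call. = FALSE)
  if (wind_min < 0 || wind_min > wind_max)
    stop("need 0 <= wind_min <= wind_max", call. = FALSE)
  if (cloud_cover < 0 || cloud_cover > 100)
    stop("cloud_cover must be in [0, 100]", call. = FALSE)
  if (rh < 0 || rh > 100) stop("rh must be in [0, 100]", call. = FALSE)
  structure(list(t_min = t_min, t_max = t_max, wind_min = wind_min,
                 wind_max = wind_max, cloud_cover = cloud_cover, rh = rh,
                 reference_elevation = reference_elevation),
            class = "daily_weather")
}

#' Baseline GNP monthly weather
#'
#' The reproduction convention for the field simulations: daily ranges of
#' 20 deg C, anchored at the published typical ranges (July/August at
#' 1500 m: 4-22 deg C; June/September sit 6 deg C cooler, consistent with
#' the -10-10 deg C range above 2500 m).  Extremes at other elevations
#' follow from the -8 deg C/km lapse rate.  `warming_delta` shifts both
#' extremes uniformly (the 2100 scenario uses +5).
#'
#' @param month Month 1-12 (June-September are the modelled season).
#' @param elevation Site elevation, m.
#' @param warming_delta Uniform warming applied to both extremes, deg C.
#' @param lapse_rate deg C/km used for the elevation adjustment.
#' @param ... Passed to [daily_weather()] (wind, cloud, rh overrides).
#' @return A `daily_weather` whose extremes refer to `elevation`.
#' @export
gnp_weather <- function(month, elevation = 1500, warming_delta = 0,
                        lapse_rate = -8, ...) {
  base <- switch(as.character(month),
    "6" = c(-2, 18), "7" = c(4, 22), "8" = c(4, 22), "9" = c(-2, 18),
    stop("gnp_weather defines the June-September field season", call. = FALSE))
  shift <- lapse_rate * (elevation - 1500) / 1000 + warming_delta
  daily_weather(t_min = base[1] + shift, t_max = base[2] + shift,
                reference_elevation = elevation, ...)
}
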
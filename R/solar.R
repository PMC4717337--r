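# Solar geometry, clear-sky radiation on slopes, and available activity hours.
#
# All times are local solar time (solar noon = 12.0); the coupled models
# work on a representative "average day" per month.

#' Solar declination
#'
#' @param day_of_year Integer day of year (1-366).
#' @return Declination in degrees (Cooper's formula).
#' @export
solar_declination <- function(day_of_year) {
  23.45 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Solar elevation angle
#'
#' @param latitude Degrees north.
#' @param day_of_year Integer day of year.
#' @param hour Local solar time in hours (0-24, fractional allowed).
#' @return Elevation above the horizon in degrees (negative at night).
#' @export
solar_elevation <- function(latitude, day_of_year, hour) {
  if (any(abs(latitude) > 90)) stop("|latitude| must be <= 90", call. = FALSE)
  decl <- solar_declination(day_of_year) * pi / 180
  lat <- latitude * pi / 180
  h_angle <- (hour - 12) * 15 * pi / 180
  sin_el <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(h_angle)
  asin(pmin(1, pmax(-1, sin_el))) * 180 / pi
}

#' Solar azimuth (degrees clockwise from north)
#' @inheritParams solar_elevation
#' @export
solar_azimuth <- function(latitude, day_of_year, hour) {
  decl <- solar_declination(day_of_year) * pi / 180
  lat <- latitude * pi / 180
  h_angle <- (hour - 12) * 15 * pi / 180
  el <- solar_elevation(latitude, day_of_year, hour) * pi / 180
  cos_az <- (sin(decl) - sin(el) * sin(lat)) / (cos(el) * cos(lat))
  az <- acos(pmin(1, pmax(-1, cos_az))) * 180 / pi
  ifelse(hour <= 12, az, 360 - az)
}

#' Sunrise, solar noon and sunset for a day
#'
#' Times are local solar hours; `threshold_deg` lets the same routine find
#' twilight boundaries (e.g. -6 for civil twilight).
#'
#' @inheritParams solar_elevation
#' @param threshold_deg Elevation threshold defining "up" (default 0).
#' @return List with `sunrise`, `noon`, `sunset`, `day_length` (hours) and
#'   `polar` flag ("day"/"night"/"none") when the sun never crosses the
#'   threshold.
#' @export
sun_events <- function(latitude, day_of_year, threshold_deg = 0) {
  decl <- solar_declination(day_of_year) * pi / 180
  lat <- latitude * pi / 180
  cos_h0 <- (sin(threshold_deg * pi / 180) - sin(lat) * sin(decl)) /
    (cos(lat) * cos(decl))
  if (cos_h0 <= -1) {
    return(list(sunrise = 0, noon = 12, sunset = 24, day_length = 24,
                polar = "day"))
  }
  if (cos_h0 >= 1) {
    return(list(sunrise = NA_real_, noon = 12, sunset = NA_real_,
                day_length = 0, polar = "night"))
  }
  h0 <- acos(cos_h0) * 180 / pi / 15  # half day length in hours
  list(sunrise = 12 - h0, noon = 12, sunset = 12 + h0, day_length = 2 * h0,
       polar = "none")
}

#' Clear-sky direct-beam irradiance
#'
#' Beam-normal irradiance (W/m^2) from a Beer-law atmosphere with
#' configurable broadband transmissivity; Kasten-Young air mass keeps low
#' sun finite.
#'
#' @param elevation_deg Solar elevation, degrees.
#' @param transmissivity Broadband transmissivity.
#' @param solar_constant W/m^2.
#' @return Direct normal irradiance, W/m^2 (0 below the horizon).
#' @export
clear_sky_direct_normal <- function(elevation_deg, transmissivity = 0.70,
                                    solar_constant = SOLAR_CONSTANT) {
  if (elevation_deg <= 0) return(0)
  zen <- 90 - elevation_deg
  m <- 1 / (cos(zen * pi / 180) + 0.50572 * (96.07995 - zen)^-1.6364)
  solar_constant * transmissivity^m
}

#' Solar radiation on a slope
#'
#' Clear-sky direct beam projected onto the site's slope/aspect plane plus
#' an isotropic diffuse component; cloud cover attenuates the direct beam
#' (transmitted fraction `1 - 0.65 c^2`) and returns half of the depleted
#' energy as extra diffuse.
#'
#' @param site A [pika_site()] object.
#' @param day_of_year Integer day of year.
#' @param hour Local solar hour.
#' @param cloud_cover Cloud cover in percent (0-100).
#' @param transmissivity Broadband clear-sky beam transmissivity.
#' @param twilight_deg Twilight band for the `twilight` flag (degrees below
#'   the horizon, positive number).
#' @return List: `solar_direct` (W/m^2 on the slope plane), `solar_diffuse`
#'   (W/m^2), `dni` (beam-normal), `elevation` (deg), `sun_up`, `twilight`.
#' @export
solar_on_slope <- function(site, day_of_year, hour, cloud_cover = 0,
                           transmissivity = 0.70, twilight_deg = 6) {
  el <- solar_elevation(site$latitude, day_of_year, hour)
  sun_up <- el > 0
  twil <- !sun_up && el > -abs(twilight_deg)
  if (!sun_up) {
    return(list(solar_direct = 0, solar_diffuse = 0, dni = 0,
                elevation = el, sun_up = FALSE, twilight = twil))
  }
  c_frac <- cloud_cover / 100
  dni_clear <- clear_sky_direct_normal(el, transmissivity)
  beam_trans <- 1 - 0.65 * c_frac^2
  dni <- dni_clear * beam_trans

  az <- solar_azimuth(site$latitude, day_of_year, hour)
  el_r <- el * pi / 180
  az_r <- az * pi / 180
  beta <- site$slope * pi / 180
  gamma <- site$aspect * pi / 180
  # cosine of incidence on the tilted plane
  cos_inc <- sin(el_r) * cos(beta) +
    cos(el_r) * sin(beta) * cos(az_r - gamma)
  direct_slope <- dni * max(0, cos_inc)

  # isotropic diffuse: scattered share of the extinguished clear beam, plus
  # half of the cloud-depleted direct energy
  diffuse_clear <- 0.30 * (SOLAR_CONSTANT - dni_clear) *
    sin(el_r) * (SOLAR_CONSTANT * transmissivity / SOLAR_CONSTANT)
  diffuse <- diffuse_clear + 0.5 * dni_clear * (1 - beam_trans) * sin(el_r)

  list(solar_direct = direct_slope, solar_diffuse = diffuse, dni = dni,
       elevation = el, sun_up = TRUE, twilight = FALSE)
}

#' Available above-talus activity hours (diurnal + crepuscular)
#'
#' Counts the whole hours of the representative mid-month day whose
#' top-of-the-hour instant has the sun above a crepuscular threshold.  The
#' default threshold (-16 degrees, between nautical and astronomical
#' twilight) reproduces the 21 h (June, July) and 19 h (August) of
#' available activity time at the Glacier National Park study latitude;
#' pikas there are active well before civil dawn.
#'
#' @param latitude Degrees north (a [pika_site()] is also accepted).
#' @param month Month number 1-12.
#' @param twilight_deg Crepuscular threshold, degrees below the horizon
#'   (positive number; 0 counts strict daylight only).
#' @return Integer count of available hours, with attribute `hours` giving
#'   the hour marks counted.
#' @export
available_hours <- function(latitude, month, twilight_deg = 16) {
  if (is.list(latitude)) latitude <- latitude$latitude
  if (month < 1 || month > 12) stop("month must be in 1..12", call. = FALSE)
  doy <- mid_month_doy(month)
  marks <- 0:23
  el <- solar_elevation(latitude, doy, marks)
  ok <- el >= -abs(twilight_deg)
  structure(sum(ok), hours = marks[ok])
}

mid_month_doy <- function(month) {
  cum <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  cum[month] + 15
}
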
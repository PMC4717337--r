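# The animal model: morphology, fur, physiology, and derived geometry.

#' Construct a pika animal model
#'
#' Morphological and physiological parameters of the simulated American
#' pika.  Fur properties default to the measured-specimen values treated as
#' a 150 g reference; field animals scale fur length and depth linearly
#' with mass (a 120 g pika has 20% shorter and shallower hair than a 150 g
#' pika), while the metabolic-chamber reference animal wears the specimen
#' fur unscaled (`scale_fur_with_mass = FALSE`).  Winter pelage is 50%
#' longer than summer, and fur depth is always 50% of fur length.  BMR is
#' anchored at 0.923 W for 109 g and scales allometrically with
#' mass^0.75.  Fur density, hair diameter and reflectivity are assumed
#' values (the source morphometrics are not published) calibrated against
#' the published chamber anchors; see the methods vignette.
#'
#' @param mass_g Body mass in grams (chamber 109; field 120/150/180).
#' @param pelage `"summer"` or `"winter"` (winter fur length = 1.5 x summer).
#' @param shape_ratio Prolate ellipsoid a:b ratio (chamber 1.5 or 2.25;
#'   field 2.25; elongation limit 3).
#' @param fur_length_dorsal_mm,fur_length_ventral_mm Summer fur lengths at
#'   the 150 g reference mass.
#' @param fur_density_cm2 Hairs per cm^2.
#' @param hair_diameter_um Hair diameter, micrometres.
#' @param fur_reflectivity Solar reflectivity of the pelt (fraction).
#' @param flesh_conductivity Vasoconstricted (resting) flesh thermal
#'   conductivity, W/(m K).
#' @param flesh_conductivity_max Fully vasodilated value, W/(m K).
#' @param o2_extraction Oxygen extraction efficiency, percent.
#' @param core_temp,core_temp_min,core_temp_max Core temperature and its
#'   regulated bounds, deg C (nominal 40.1, hard max 43 just below the
#'   upper-lethal 43.1).
#' @param bmr_w Basal metabolic rate in W; default Kleiber-scaled from
#'   0.923 W at 109 g.
#' @param fur_scale Extra multiplier on fur length/depth (e.g. 1.2 for the
#'   "20% longer and thicker fur" scenario; also scales density).
#' @param scale_fur_with_mass Scale fur dimensions by mass/150?
#' @param flesh_density kg/m^3.
#' @param config Named list of biophysical constants overriding
#'   [endotherm_config()] entries.
#' @return Object of class `pika_animal`.
#' @export
pika_animal <- function(mass_g = 150, pelage = c("summer", "winter"),
                        shape_ratio = 2.25,
                        fur_length_dorsal_mm = 33,
                        fur_length_ventral_mm = 25,
                        fur_density_cm2 = 2300,
                        hair_diameter_um = 32,
                        fur_reflectivity = 0.25,
                        flesh_conductivity = 0.5,
                        flesh_conductivity_max = 2.8,
                        o2_extraction = 20,
                        core_temp = 40.1, core_temp_min = 38,
                        core_temp_max = 43,
                        bmr_w = NULL, fur_scale = 1,
                        scale_fur_with_mass = TRUE,
                        flesh_density = 1000,
                        config = list()) {
  pelage <- match.arg(pelage)
  stopifnot(mass_g > 0, shape_ratio >= 1, fur_density_cm2 >= 0,
            hair_diameter_um > 0, flesh_conductivity > 0,
            flesh_conductivity_max >= flesh_conductivity,
            o2_extraction > 0, o2_extraction <= 100, flesh_density > 0,
            fur_scale > 0)
  if (!(core_temp_min <= core_temp && core_temp <= core_temp_max))
    stop("need core_temp_min <= core_temp <= core_temp_max", call. = FALSE)
  if (fur_reflectivity < 0 || fur_reflectivity > 1)
    stop("fur_reflectivity is a fraction in [0, 1]", call. = FALSE)
  pel_mult <- if (pelage == "winter") 1.5 else 1
  mass_mult <- if (scale_fur_with_mass) mass_g / 150 else 1
  len_d <- fur_length_dorsal_mm * pel_mult * mass_mult * fur_scale
  len_v <- fur_length_ventral_mm * pel_mult * mass_mult * fur_scale
  if (is.null(bmr_w)) bmr_w <- 0.923 * (mass_g / 109)^0.75
  cfg <- utils::modifyList(endotherm_config(), config)
  structure(list(
    mass_g = mass_g, pelage = pelage, shape_ratio = shape_ratio,
    fur_length_dorsal_mm = len_d, fur_length_ventral_mm = len_v,
    fur_depth_dorsal_mm = 0.5 * len_d, fur_depth_ventral_mm = 0.5 * len_v,
    fur_density_cm2 = fur_density_cm2 * fur_scale,
    hair_diameter_um = hair_diameter_um,
    fur_reflectivity = fur_reflectivity,
    flesh_conductivity = flesh_conductivity,
    flesh_conductivity_max = flesh_conductivity_max,
    o2_extraction = o2_extraction,
    core_temp = core_temp, core_temp_min = core_temp_min,
    core_temp_max = core_temp_max,
    bmr_w = bmr_w, flesh_density = flesh_density, config = cfg
  ), class = "pika_animal")
}

#' Reference metabolic-chamber animal (109 g)
#'
#' The chamber validation configuration: mean experimental mass 109 g,
#' specimen fur unscaled, resting posture.
#'
#' @param shape_ratio Ellipsoid a:b ratio (the chamber runs used 1.5 and
#'   2.25).
#' @param ... Overrides passed to [pika_animal()].
#' @export
chamber_animal <- function(shape_ratio = 2.25, ...) {
  pika_animal(mass_g = 109, shape_ratio = shape_ratio,
              scale_fur_with_mass = FALSE, ...)
}

#' Biophysical constants of the endotherm model
#'
#' Defaults are the package's documented assumptions (see the methods
#' vignette for rationale and calibration anchors).
#'
#' @return Named list: `emissivity`, `exposure_fraction` (fraction of the
#'   surface exchanging with the environment; the rest is in ground
#'   contact), `k_hair_cross` (across-fibre hair conductivity, W/m K),
#'   `chi_extinction` (optical extinction efficiency of hair),
#'   `wind_penetration` (coefficient of the `1 + c*u^0.8` fur disruption
#'   factor), `skin_evap_fraction` (cutaneous share of q_gen),
#'   `exhale_recovery` (nasal countercurrent temperature recovery),
#'   `view_sky`/`view_ground` (radiative view factors),
#'   `conv_enhancement` (multiplier on the convective Nusselt number),
#'   `solar_silhouette_factor` (effective beam interception relative to the
#'   plan-area silhouette; crouching and fur backscatter reduce it),
#'   `activity_fmr_threshold` (FMR/BMR needed for activity).
#' @export
endotherm_config <- function() {
  list(emissivity = 0.95,
       exposure_fraction = 0.80,
       k_hair_cross = 0.023,
       chi_extinction = 0.67,
       wind_penetration = 1.7,
       wind_penetration_depth_exp = 0.18,
       skin_evap_fraction = 0.015,
       exhale_recovery = 0.05,
       view_sky = 0.5, view_ground = 0.5,
       solar_silhouette_factor = 0.35,
       conv_enhancement = 0.9,
       activity_fmr_threshold = 1.5)
}

# Prolate-spheroid geometry at a given posture (a:b ratio) and fur depth.
animal_geometry <- function(animal, shape_ratio = animal$shape_ratio) {
  vol <- animal$mass_g / 1000 / animal$flesh_density  # m^3
  s <- shape_ratio
  b <- (3 * vol / (4 * pi * s))^(1 / 3)
  a <- s * b
  d_fur <- 0.5 * (animal$fur_depth_dorsal_mm + animal$fur_depth_ventral_mm) / 1000
  list(a = a, b = b, d_fur = d_fur,
       area_skin = prolate_area(a, b),
       area_outer = prolate_area(a + d_fur, b + d_fur),
       area_sil = pi * (a + d_fur) * (b + d_fur),
       d_char = vol^(1 / 3))
}

prolate_area <- function(a, b) {
  if (abs(a - b) < 1e-12) return(4 * pi * a^2)
  e <- sqrt(1 - (b / a)^2)
  2 * pi * b^2 * (1 + (a / b) * asin(e) / e)
}
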
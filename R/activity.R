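# Daily above-talus activity budgets, the warming-scenario comparison and
# the heat-wave refuge simulation: microclimate and endotherm models
# coupled hour by hour.

# Animal-height environments for one microclimate hour.
#
# Activity is assessed in the sheltered shaded microsite a pika selects
# among the rocks: radiant surroundings at the local animal-height
# temperature and a steady interstitial draft (default 0.6 m/s) only
# weakly coupled to the open above-talus wind.  `sun_exposed_env()` is
# the open surface in full sun and unattenuated wind, used for acute
# heat-stress assessment.
microsite_env <- function(mc_row, rh, microsite_wind = 0.6) {
  t <- mc_row$t_air_animal_C
  env_state(t_air = t, t_ground = t, t_sky = t, wind = microsite_wind,
            rh = rh, in_shade = TRUE)
}

sun_exposed_env <- function(mc_row, site, rh) {
  t_sky <- (mc_row$sky_ir_down_Wm2 / SIGMA_SB)^0.25 - 273.15
  env_state(t_air = mc_row$t_air_animal_C,
            t_ground = mc_row$t_surface_C,
            t_sky = t_sky,
            wind = mc_row$wind_animal_ms,
            rh = rh,
            solar_dni = mc_row$solar_direct_Wm2,
            solar_elevation = 90,
            solar_diffuse = mc_row$solar_diffuse_Wm2,
            ground_reflectivity = site$substrate_reflectivity,
            in_shade = FALSE)
}

#' Field activity-threshold temperature
#'
#' Sweeps air temperature in the field activity microsite (sheltered
#' shade, radiant surroundings at air temperature) and returns the
#' temperature at which the maximum allowable FMR/BMR falls to `level`.
#' With the default 1.5 level and the 150 g summer-fur field animal this
#' is the behavioural temperature threshold of the coupled model.
#'
#' @param animal A [pika_animal()].
#' @param level FMR/BMR level defining the threshold (1.5 = activity
#'   limit, 1.0 = BMR sustainability).
#' @param wind Microsite wind, m/s.
#' @param rh Relative humidity, percent.
#' @return Threshold air temperature, deg C.
#' @export
field_activity_threshold <- function(animal, level = 1.5, wind = 0.6,
                                     rh = 50) {
  f <- function(t) {
    e <- env_state(t_air = t, t_ground = t, t_sky = t, wind = wind,
                   rh = rh, in_shade = TRUE)
    max_allowable_activity(animal, e)$max_allowable_fmr_multiple - level
  }
  stats::uniroot(f, c(-10, 45), tol = 0.005)$root
}

#' Daily above-talus activity budget
#'
#' For every available hour (diurnal + crepuscular) of the representative
#' day, evaluates [max_allowable_activity()] under that hour's shaded
#' above-talus microclimate and counts the hours whose maximum allowable
#' FMR/BMR reaches 1.5.
#'
#' @param animal A [pika_animal()].
#' @param site A [pika_site()].
#' @param month Month (6-9).
#' @param weather Optional [daily_weather()]; default [gnp_weather()] for
#'   the site elevation.
#' @param warming_delta Uniform warming (deg C) applied to the daily
#'   extremes (the 2100 scenario uses +5).
#' @param microclimate Optional precomputed [microclimate_day()] (shaded).
#' @param microsite_wind Interstitial draft of the activity microsite,
#'   m/s.
#' @return Object of class `activity_budget`: `available_hours`,
#'   `allowable_hours`, `restriction_pct`
#'   (= 100*(available-allowable)/available), and data.frame `hours`
#'   (hour, t_air_animal_C, fmr_multiple, allowable).
#' @export
daily_activity_budget <- function(animal, site, month, weather = NULL,
                                  warming_delta = 0, microclimate = NULL,
                                  microsite_wind = 0.6) {
  if (is.null(weather))
    weather <- gnp_weather(month, elevation = site$elevation,
                           warming_delta = warming_delta)
  else if (warming_delta != 0) {
    weather$t_min <- weather$t_min + warming_delta
    weather$t_max <- weather$t_max + warming_delta
  }
  if (is.null(microclimate))
    microclimate <- microclimate_day(site, weather, month, shade = TRUE)
  avail <- available_hours(site$latitude, month)
  marks <- attr(avail, "hours")
  rows <- lapply(marks, function(h) {
    mc <- microclimate[microclimate$hour == h, ]
    act <- tryCatch(
      max_allowable_activity(animal,
                             microsite_env(mc, weather$rh, microsite_wind)),
      error = function(e) stop("hour ", h, ": ", conditionMessage(e),
                               call. = FALSE))
    data.frame(hour = h, t_air_animal_C = mc$t_air_animal_C,
               fmr_multiple = act$max_allowable_fmr_multiple,
               allowable = act$active_possible)
  })
  hours <- do.call(rbind, rows)
  allowable <- sum(hours$allowable)
  structure(list(
    available_hours = as.integer(avail),
    allowable_hours = as.integer(allowable),
    restriction_pct = 100 * (as.integer(avail) - allowable) / as.integer(avail),
    hours = hours, month = month, warming_delta = warming_delta,
    animal = animal, site = site
  ), class = "activity_budget")
}

#' Compare warming-scenario budgets with baseline
#'
#' @param baseline,scenario Lists (or single objects) of
#'   [daily_activity_budget()] results with matching `key` labels; a
#'   named list is matched by name.
#' @return data.frame: key, allowable_baseline, allowable_scenario,
#'   change_hours, change_vs_baseline_pct
#'   (= 100*(scenario-baseline)/baseline, whole-hour quantised).
#' @export
warming_scenario_comparison <- function(baseline, scenario) {
  as_list <- function(x) if (inherits(x, "activity_budget")) list(x) else x
  b <- as_list(baseline); s <- as_list(scenario)
  if (is.null(names(b))) names(b) <- paste0("run", seq_along(b))
  if (is.null(names(s))) names(s) <- paste0("run", seq_along(s))
  if (!setequal(names(b), names(s)))
    stop("baseline and scenario keys do not match", call. = FALSE)
  keys <- names(b)
  do.call(rbind, lapply(keys, function(k) {
    ab <- b[[k]]$allowable_hours; as_ <- s[[k]]$allowable_hours
    data.frame(key = k, allowable_baseline = ab, allowable_scenario = as_,
               change_hours = as_ - ab,
               change_vs_baseline_pct = 100 * (as_ - ab) / ab)
  }))
}

#' Heat-wave refuge simulation
#'
#' Simulates a heat wave (July means + `heatwave_delta`) and evaluates,
#' for every hour, whether the animal can sustain BMR (and the full 1.5
#' activity threshold) exposed on the sunlit above-talus surface and
#' inside the talus at each refuge depth.  Refuge cavities are dark,
#' radiatively enclosed at the substrate temperature of their depth, and
#' ventilated by the same interstitial draft as the activity microsite;
#' the refuge column is driven by the shaded surface balance
#' (interstices are not directly irradiated).
#'
#' @param animal A [pika_animal()].
#' @param site A [pika_site()] (depths from `site$refuge_depths`).
#' @param month Month of the heat wave (default 7).
#' @param heatwave_delta Warming of the daily extremes above the monthly
#'   means, deg C (default +10).
#' @param weather Optional explicit [daily_weather()] already including
#'   the heat wave.
#' @return Object of class `refuge_feasibility`: data.frame `hours` with
#'   one row per hour x location (`location`, `hour`, `t_local_C`,
#'   `fmr_multiple`, `bmr_sustainable`, `active_possible`) and the
#'   `microclimate` used.
#' @export
heatwave_refuge_simulation <- function(animal, site, month = 7,
                                       heatwave_delta = 10,
                                       weather = NULL, refuge_wind = 0.6) {
  if (is.null(weather))
    weather <- gnp_weather(month, elevation = site$elevation,
                           warming_delta = heatwave_delta)
  mc <- microclimate_day(site, weather, month, shade = TRUE)
  mc_sun <- microclimate_day(site, weather, month, shade = FALSE)
  depths <- site$refuge_depths
  sub_cols <- paste0("t_sub_", round(depths * 100), "cm_C")
  missing_d <- !sub_cols %in% names(mc)
  if (any(missing_d))
    stop("depth(s) not in microclimate profile: ",
         paste(depths[missing_d], collapse = ", "), call. = FALSE)
  rows <- list()
  for (h in 0:23) {
    r <- mc[mc$hour == h, ]
    r_sun <- mc_sun[mc_sun$hour == h, ]
    surf <- max_allowable_activity(animal,
                                   sun_exposed_env(r_sun, site, weather$rh))
    rows[[length(rows) + 1]] <- data.frame(
      location = "surface", hour = h, t_local_C = r_sun$t_air_animal_C,
      fmr_multiple = surf$max_allowable_fmr_multiple,
      bmr_sustainable = surf$bmr_sustainable,
      active_possible = surf$active_possible)
    for (i in seq_along(depths)) {
      tl <- r[[sub_cols[i]]]
      cav <- max_allowable_activity(animal,
        env_state(t_air = tl, t_ground = tl, t_sky = tl,
                  wind = refuge_wind, rh = weather$rh))
      rows[[length(rows) + 1]] <- data.frame(
        location = sprintf("%.0fcm", depths[i] * 100), hour = h,
        t_local_C = tl, fmr_multiple = cav$max_allowable_fmr_multiple,
        bmr_sustainable = cav$bmr_sustainable,
        active_possible = cav$active_possible)
    }
  }
  structure(list(hours = do.call(rbind, rows), microclimate = mc,
                 depths = depths),
            class = "refuge_feasibility")
}
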
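# Metabolic-chamber simulations and parameter sensitivity analyses.

#' Simulate a metabolic-chamber curve
#'
#' Runs [solve_required_metabolic_rate()] across a range of chamber air
#' temperatures (blackbody walls, constant wind) and reports the
#' Scholander-type curve with its thermal neutral zone.
#'
#' @param animal A [pika_animal()] (typically [chamber_animal()]).
#' @param t_range Air temperatures to evaluate, deg C (within [-20, 45]).
#' @param wind Chamber wind, m/s.
#' @param rh Chamber humidity, percent.
#' @return Object of class `metabolic_curve`: data.frame `points`
#'   (`t_air`, `q_gen_W`, `feasible`), list `tnz` (`lct`, `uct`), and the
#'   `plateau_W` (mean rate over the TNZ points).  Infeasible (overheated)
#'   temperatures truncate the curve with a warning.
#' @export
simulate_chamber_curve <- function(animal, t_range = seq(-15, 30, by = 1),
                                   wind = 0.1, rh = 60) {
  if (any(t_range < -20 | t_range > 45))
    stop("t_range must lie within [-20, 45] deg C", call. = FALSE)
  t_range <- sort(t_range)
  sol <- lapply(t_range, function(t)
    solve_required_metabolic_rate(animal, chamber_env(t, wind, rh)))
  feas <- vapply(sol, `[[`, logical(1), "feasible")
  q <- vapply(sol, `[[`, numeric(1), "q_gen")
  if (any(!feas))
    warning("curve truncated: animal overheats at ",
            sum(!feas), " temperature(s)")
  pts <- data.frame(t_air = t_range, q_gen_W = q, feasible = feas)
  tnz <- thermal_neutral_zone(animal, wind = wind, rh = rh)
  in_tnz <- feas & t_range >= tnz$lct & (is.na(tnz$uct) | t_range <= tnz$uct)
  plateau <- if (any(in_tnz)) mean(q[in_tnz]) else animal$bmr_w
  structure(list(points = pts, tnz = tnz, plateau_W = plateau),
            class = "metabolic_curve")
}

#' Parameter sensitivity table
#'
#' Evaluates the change in required metabolic rate when one animal
#' parameter moves from a low to a high value, all else at base values.
#' Each sweep is a list with `parameter`, `low`, `high`, and optionally
#' `t_air` (default 0 deg C) and `metric` (`"W"` whole-animal or `"W_g"`
#' mass-specific).
#'
#' @param animal Base [pika_animal()].
#' @param sweeps List of sweep specifications.
#' @param wind,rh Chamber conditions.
#' @param env Optional [env_state()] overriding the chamber (e.g. the
#'   500 W/m^2 overhead-sun configuration for reflectivity).
#' @return data.frame: parameter, low, high, t_air, metric, low_value,
#'   high_value, percent_change (100 * (high - low)/low).
#' @export
sensitivity_table <- function(animal, sweeps, wind = 0.1, rh = 60,
                              env = NULL) {
  known <- c("fur_density_cm2", "o2_extraction", "flesh_conductivity",
             "core_temp", "shape_ratio", "fur_reflectivity", "mass_g",
             "hair_diameter_um", "fur_length_dorsal_mm")
  rows <- lapply(sweeps, function(sw) {
    if (!sw$parameter %in% known)
      stop("unknown sweep parameter: ", sw$parameter, call. = FALSE)
    t_air <- sw$t_air %||% 0
    metric <- sw$metric %||% "W"
    sw_env <- sw$env %||% env
    vals <- vapply(c(sw$low, sw$high), function(v) {
      an <- set_animal_parameter(animal, sw$parameter, v)
      e <- if (is.null(sw_env)) chamber_env(t_air, wind, rh) else sw_env
      q <- solve_required_metabolic_rate(an, e)$q_gen
      if (metric == "W_g") q / an$mass_g else q
    }, numeric(1))
    data.frame(parameter = sw$parameter, low = sw$low, high = sw$high,
               t_air = t_air, metric = metric,
               low_value = vals[1], high_value = vals[2],
               percent_change = 100 * (vals[2] - vals[1]) / vals[1])
  })
  do.call(rbind, rows)
}

set_animal_parameter <- function(animal, parameter, value) {
  args <- list(mass_g = animal$mass_g, pelage = "summer",
               shape_ratio = animal$shape_ratio,
               fur_density_cm2 = animal$fur_density_cm2,
               hair_diameter_um = animal$hair_diameter_um,
               fur_reflectivity = animal$fur_reflectivity,
               flesh_conductivity = animal$flesh_conductivity,
               flesh_conductivity_max = animal$flesh_conductivity_max,
               o2_extraction = animal$o2_extraction,
               core_temp = animal$core_temp,
               core_temp_min = animal$core_temp_min,
               core_temp_max = animal$core_temp_max,
               bmr_w = animal$bmr_w, flesh_density = animal$flesh_density,
               config = animal$config)
  if (parameter == "core_temp") {
    args$core_temp <- value
    args$core_temp_min <- min(animal$core_temp_min, value)
    args$core_temp_max <- max(animal$core_temp_max, value)
  } else if (parameter == "mass_g") {
    args$mass_g <- value
    args$bmr_w <- NULL  # rescale allometrically
  } else if (parameter == "flesh_conductivity") {
    args$flesh_conductivity <- value
    args$flesh_conductivity_max <- max(value,
                                       animal$flesh_conductivity_max)
  } else {
    args[[parameter]] <- value
  }
  # fur lengths already folded into the animal: pass through unscaled
  # stored lengths/density are final values; disable re-scaling multipliers
  an <- do.call(pika_animal, c(args, list(scale_fur_with_mass = FALSE,
    fur_length_dorsal_mm = animal$fur_length_dorsal_mm,
    fur_length_ventral_mm = animal$fur_length_ventral_mm)))
  an$pelage <- animal$pelage
  an
}

#' The paper-standard sensitivity sweep set
#'
#' The eight chamber sensitivity analyses: core temperature 38-43 deg C
#' (mass-specific), posture 3:2 to 3:1, fur density 250-3000 and
#' 3000-15000 hairs/cm^2, O2 extraction 5-30%, flesh conductivity
#' 0.5-2.8 W/mK, reflectivity 15-90% under 500 W/m^2 overhead sun, and
#' mass 109-150 g (mass-specific, cold).
#'
#' @param t_air Evaluation temperature for sweeps whose temperature the
#'   analysis leaves open (default 0 deg C).
#' @return List of sweep specifications for [sensitivity_table()].
#' @export
standard_sensitivity_sweeps <- function(t_air = 0) {
  list(
    list(parameter = "core_temp", low = 38, high = 43, t_air = t_air,
         metric = "W_g"),
    list(parameter = "shape_ratio", low = 1.5, high = 3.0, t_air = t_air),
    list(parameter = "fur_density_cm2", low = 250, high = 3000,
         t_air = 0),
    list(parameter = "fur_density_cm2", low = 3000, high = 15000,
         t_air = 0),
    list(parameter = "o2_extraction", low = 5, high = 30, t_air = t_air),
    list(parameter = "flesh_conductivity", low = 0.5, high = 2.8,
         t_air = t_air),
    list(parameter = "fur_reflectivity", low = 0.15, high = 0.90,
         t_air = t_air,
         env = env_state(t_air = t_air, wind = 0.1, solar_dni = 500,
                         solar_elevation = 90)),
    list(parameter = "mass_g", low = 109, high = 150, t_air = t_air,
         metric = "W_g")
  )
}
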
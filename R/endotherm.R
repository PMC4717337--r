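# Steady-state heat balance of the furred ellipsoidal endotherm:
# Q_in + Q_gen = Q_out + Q_st with Q_st = 0.
#
# Network: core --(flesh)--> skin, then two parallel shells:
#   * a fur-covered fraction (coverage phi): skin -> fur layer -> outer
#     surface -> convection + IR to the environment;
#   * an uncovered fraction (1 - phi, sparse pelts): skin exchanging
#     directly.
# Radiation uses exact sigma*T^4 exchange (h_r fixed-point iterated), so
# reported fluxes close the balance to numerical tolerance.

#' Environment state around the animal
#'
#' @param t_air Air temperature at animal height, deg C.
#' @param t_ground Radiant ground-surface temperature, deg C.
#' @param t_sky Effective radiant sky temperature, deg C.
#' @param wind Wind at animal height, m/s.
#' @param rh Relative humidity, percent.
#' @param solar_dni Direct-beam irradiance normal to the beam, W/m^2.
#' @param solar_elevation Sun elevation, degrees (90 = overhead).
#' @param solar_diffuse Diffuse irradiance, W/m^2.
#' @param ground_reflectivity Shortwave reflectivity of the ground.
#' @param in_shade If TRUE the direct beam is removed.
#' @param suppress_evaporation Disable all evaporative losses (used by
#'   degenerate-balance checks).
#' @return Object of class `env_state`.
#' @export
env_state <- function(t_air, t_ground = t_air, t_sky = t_air, wind = 0.1,
                      rh = 60, solar_dni = 0, solar_elevation = 90,
                      solar_diffuse = 0, ground_reflectivity = 0.25,
                      in_shade = FALSE, suppress_evaporation = FALSE) {
  stopifnot(wind >= 0, solar_dni >= 0, solar_diffuse >= 0)
  assert_finite(c(t_air, t_ground, t_sky))
  structure(list(t_air = t_air, t_ground = t_ground, t_sky = t_sky,
                 wind = wind, rh = rh, solar_dni = solar_dni,
                 solar_elevation = solar_elevation,
                 solar_diffuse = solar_diffuse,
                 ground_reflectivity = ground_reflectivity,
                 in_shade = in_shade,
                 suppress_evaporation = suppress_evaporation),
            class = "env_state")
}

#' Metabolic-chamber environment
#'
#' Blackbody chamber: walls at air temperature, no solar, constant wind.
#' @param t_air Chamber temperature, deg C.
#' @param wind Wind speed, m/s (experimental 0.1).
#' @param rh Chamber humidity, percent.
#' @export
chamber_env <- function(t_air, wind = 0.1, rh = 60) {
  env_state(t_air = t_air, t_ground = t_air, t_sky = t_air, wind = wind,
            rh = rh)
}

# Physiological/behavioural state used by the thermoregulatory cascade.
animal_state <- function(animal, posture = animal$shape_ratio,
                         k_flesh = animal$flesh_conductivity,
                         t_core = animal$core_temp) {
  list(posture = posture, k_flesh = k_flesh, t_core = t_core)
}

# Forward pass: given q_gen and a state, solve the linear two-node shell
# network and return the implied core temperature plus flux components.
balance_forward <- function(animal, env, q_gen, state) {
  cfg <- animal$config
  geo <- animal_geometry(animal, state$posture)
  f_exp <- cfg$exposure_fraction
  fur <- fur_layer_resistance(animal$fur_density_cm2, animal$hair_diameter_um,
                              1000 * geo$d_fur, wind = env$wind,
                              t_mean_c = env$t_air, config = cfg)
  phi <- min(max(fur$coverage, 1e-6), 1 - 1e-9)
  a_skin <- geo$area_skin; a_out <- geo$area_outer
  a_mean <- 0.5 * (a_skin + a_out)
  r_body <- geo$b / (2 * state$k_flesh * a_skin)

  # evaporation coefficients (both proportional to q_gen)
  c_s <- if (env$suppress_evaporation) 0 else cfg$skin_evap_fraction
  c_r <- if (env$suppress_evaporation || q_gen <= 0) 0 else
    respiratory_evaporation(1, env$t_air, env$rh, animal$o2_extraction,
                            state$t_core, cfg$exhale_recovery)
  q_resp <- c_r * q_gen
  q_skin_evap <- c_s * q_gen
  f_body <- q_gen - q_resp

  # solar absorption split between covered (outer) and bare (skin) paths
  s_dir <- if (env$in_shade) 0 else env$solar_dni
  sin_el <- sin(max(0, env$solar_elevation) * pi / 180)
  glob_h <- s_dir * sin_el + env$solar_diffuse
  q_sol <- (1 - animal$fur_reflectivity) *
    (cfg$solar_silhouette_factor * geo$area_sil * s_dir +
     0.5 * a_out * f_exp * env$solar_diffuse +
     0.5 * a_out * f_exp * env$ground_reflectivity * glob_h)
  q_sol_dense <- phi * q_sol
  q_sol_bare <- (1 - phi) * q_sol

  eps <- cfg$emissivity
  t_r4 <- cfg$view_sky * c_to_k(env$t_sky)^4 +
    cfg$view_ground * c_to_k(env$t_ground)^4
  t_r <- t_r4^0.25 - 273.15
  g_fur <- fur$k_effective * a_mean * f_exp * phi /
    max(geo$d_fur, 1e-9)

  # convective coefficient (forced + free floor), iterated with radiation
  t_s <- env$t_air + 3; t_o <- env$t_air + 1
  k_a <- air_conductivity(env$t_air)
  nu_a <- air_kinematic_viscosity(env$t_air)
  re <- max(env$wind, 0.02) * geo$d_char / nu_a
  nu_forced <- (2 + 0.6 * sqrt(re) * AIR_PRANDTL^(1 / 3))
  for (it in 1:8) {
    dt_free <- max(abs(t_o - env$t_air), abs(t_s - env$t_air), 0.1)
    ra <- 9.81 / c_to_k(env$t_air) * dt_free * geo$d_char^3 /
      (nu_a * 2.11e-5)
    nu_free <- 2 + 0.5 * ra^0.25
    h_c <- cfg$conv_enhancement * max(nu_forced, nu_free) * k_a / geo$d_char
    h_ro <- eps * SIGMA_SB * (c_to_k(t_o)^2 + c_to_k(t_r)^2) *
      (c_to_k(t_o) + c_to_k(t_r))
    h_rs <- eps * SIGMA_SB * (c_to_k(t_s)^2 + c_to_k(t_r)^2) *
      (c_to_k(t_s) + c_to_k(t_r))
    g_co <- h_c * a_out * f_exp * phi
    g_ro <- h_ro * a_out * f_exp * phi
    g_cb <- h_c * a_skin * f_exp * (1 - phi)
    g_rb <- h_rs * a_skin * f_exp * (1 - phi)
    # node equations (linear in t_s, t_o):
    # skin : f_body + q_sol_bare - q_skin_evap
    #        = g_fur (t_s - t_o) + g_cb (t_s - t_air) + g_rb (t_s - t_r)
    # outer: g_fur (t_s - t_o) + q_sol_dense = g_co (t_o - t_air) + g_ro (t_o - t_r)
    a11 <- g_fur + g_cb + g_rb; a12 <- -g_fur
    b1 <- f_body + q_sol_bare - q_skin_evap + g_cb * env$t_air + g_rb * t_r
    a21 <- g_fur; a22 <- -(g_fur + g_co + g_ro)
    b2 <- -q_sol_dense - g_co * env$t_air - g_ro * t_r
    det <- a11 * a22 - a12 * a21
    t_s_new <- (b1 * a22 - a12 * b2) / det
    t_o_new <- (a11 * b2 - b1 * a21) / det
    if (abs(t_s_new - t_s) < 1e-8 && abs(t_o_new - t_o) < 1e-8) {
      t_s <- t_s_new; t_o <- t_o_new; break
    }
    t_s <- t_s_new; t_o <- t_o_new
  }
  t_core_implied <- t_s + f_body * r_body

  q_conv <- g_co * (t_o - env$t_air) + g_cb * (t_s - env$t_air)
  # exact Stefan-Boltzmann components (h_r construction makes these close)
  area_ro <- a_out * f_exp * phi; area_rs <- a_skin * f_exp * (1 - phi)
  q_ir_out <- eps * SIGMA_SB * (area_ro * c_to_k(t_o)^4 +
                                area_rs * c_to_k(t_s)^4)
  q_ir_in <- eps * SIGMA_SB * (area_ro + area_rs) * t_r4

  list(t_core_implied = t_core_implied, t_skin = t_s, t_outer = t_o,
       q_solar_abs = q_sol, q_ir_in = q_ir_in, q_ir_out = q_ir_out,
       q_conv = q_conv, q_evap_resp = q_resp, q_evap_skin = q_skin_evap,
       r_body = r_body, fur = fur, h_c = h_c)
}

# Root-find q_gen such that the implied core temperature equals the state
# target. Returns the (possibly negative) root; negative means the animal
# gains more heat than it can shed even at zero metabolism.
required_q_gen <- function(animal, env, state, tol = 1e-5) {
  f <- function(q) balance_forward(animal, env, q, state)$t_core_implied -
    state$t_core
  lo <- 0; hi <- max(40 * animal$bmr_w, 5)
  f_lo <- f(lo)
  if (f_lo > 0) {  # even q = 0 overshoots: extend to negative (virtual) q
    lo <- -hi
    if (f(lo) > 0) return(-Inf)
  }
  if (f(hi) < 0) {
    hi <- hi * 10
    if (f(hi) < 0) return(Inf)
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Solve the required metabolic rate
#'
#' Finds the metabolic heat production Q_gen that closes the steady-state
#' balance at the nominal core temperature.  If the root falls below BMR
#' (heat side), the thermoregulatory cascade engages in order: posture
#' elongation (toward 3:1), vasodilation (flesh conductivity to its
#' maximum), then core-temperature elevation (toward `core_temp_max`),
#' stopping at the configuration whose balance closes exactly at BMR.  If
#' the fully engaged cascade still cannot dissipate BMR the hour is
#' declared infeasible (never silently clamped).
#'
#' @param animal A [pika_animal()].
#' @param env An [env_state()].
#' @param bmr_floor If FALSE, return the raw root at the nominal state
#'   without the BMR floor or cascade (the bare balance; used e.g. for
#'   degenerate-configuration checks and LCT detection).
#' @return List of class `heat_balance_solution`: `q_gen` (W), flux
#'   components (`q_solar_abs`, `q_ir_in`, `q_ir_out`, `q_conv`,
#'   `q_evap_resp`, `q_evap_skin`), `q_stored` (always 0), `feasible`,
#'   `posture_ratio_used`, `flesh_conductivity_used`, `core_temp_used`,
#'   `t_skin`, `t_outer`, and `balance_residual` (W).
#' @export
solve_required_metabolic_rate <- function(animal, env, bmr_floor = TRUE) {
  bmr <- animal$bmr_w
  st <- animal_state(animal)
  q <- required_q_gen(animal, env, st)
  if (!bmr_floor)
    return(finish_solution(animal, env, max(0, q), st,
                           feasible = is.finite(q) && q >= 0))
  if (q >= bmr) return(finish_solution(animal, env, q, st, feasible = TRUE))

  # heat side: walk the cascade; each stage parameterised on [0, 1]
  stages <- list(
    function(x) animal_state(animal,
      posture = st$posture + x * (3.0 - st$posture),
      k_flesh = st$k_flesh, t_core = st$t_core),
    function(x) animal_state(animal, posture = 3.0,
      k_flesh = st$k_flesh + x * (animal$flesh_conductivity_max - st$k_flesh),
      t_core = st$t_core),
    function(x) animal_state(animal, posture = 3.0,
      k_flesh = animal$flesh_conductivity_max,
      t_core = st$t_core + x * (animal$core_temp_max - st$t_core))
  )
  for (stage in stages) {
    q_end <- required_q_gen(animal, env, stage(1))
    if (q_end >= bmr) {
      g <- function(x) required_q_gen(animal, env, stage(x)) - bmr
      x_star <- if (abs(g(0)) < 1e-9) 0 else
        stats::uniroot(g, c(0, 1), tol = 1e-6)$root
      st_star <- stage(x_star)
      return(finish_solution(animal, env, bmr, st_star, feasible = TRUE))
    }
  }
  st_full <- stages[[3]](1)
  q_full <- required_q_gen(animal, env, st_full)
  finish_solution(animal, env, max(0, q_full), st_full, feasible = FALSE)
}

finish_solution <- function(animal, env, q, state, feasible) {
  fb <- balance_forward(animal, env, q, state)
  resid <- fb$q_solar_abs + fb$q_ir_in + q -
    fb$q_ir_out - fb$q_conv - fb$q_evap_resp - fb$q_evap_skin
  structure(list(
    q_gen = q, q_solar_abs = fb$q_solar_abs, q_ir_in = fb$q_ir_in,
    q_ir_out = fb$q_ir_out, q_conv = fb$q_conv,
    q_evap_resp = fb$q_evap_resp, q_evap_skin = fb$q_evap_skin,
    q_stored = 0, feasible = feasible,
    posture_ratio_used = state$posture,
    flesh_conductivity_used = state$k_flesh,
    core_temp_used = state$t_core,
    t_skin = fb$t_skin, t_outer = fb$t_outer,
    balance_residual = resid
  ), class = "heat_balance_solution")
}

#' Maximum allowable activity level (FMR/BMR)
#'
#' With all heat-shedding mechanisms engaged (3:1 posture, maximum flesh
#' conductivity, core at its upper bound) returns the largest metabolic
#' rate the animal can dissipate, expressed as a multiple of BMR.
#' Activity is considered feasible when the multiple reaches the 1.5
#' threshold.
#'
#' @inheritParams solve_required_metabolic_rate
#' @return List of class `activity_assessment`:
#'   `max_allowable_fmr_multiple`, `active_possible`, `q_max` (W),
#'   `bmr_sustainable` (multiple >= 1).
#' @export
max_allowable_activity <- function(animal, env) {
  st <- animal_state(animal, posture = 3.0,
                     k_flesh = animal$flesh_conductivity_max,
                     t_core = animal$core_temp_max)
  q_max <- required_q_gen(animal, env, st)
  if (!is.finite(q_max)) q_max <- if (q_max > 0) 40 * animal$bmr_w else 0
  mult <- max(0, q_max) / animal$bmr_w
  thr <- animal$config$activity_fmr_threshold
  structure(list(max_allowable_fmr_multiple = mult,
                 active_possible = mult >= thr,
                 q_max = max(0, q_max),
                 bmr_sustainable = mult >= 1),
            class = "activity_assessment")
}

#' Thermal neutral zone of an animal in the chamber
#'
#' The upper critical temperature (UCT) is the air temperature at which
#' the resting requirement equals BMR with the thermoregulatory reserve
#' exhausted (FMR = BMR); the lower critical temperature (LCT) is where
#' the resting requirement at the nominal (vasoconstricted) state rises
#' above BMR.  Both found by bisection to 0.01 deg C.
#'
#' @param animal A [pika_animal()].
#' @param wind Chamber wind speed, m/s.
#' @param rh Chamber humidity, percent.
#' @param t_search Search interval for the critical temperatures, deg C.
#' @return List `lct`, `uct` (deg C). `uct` is `NA` with a warning if no
#'   upper critical temperature exists below the search ceiling.
#' @export
thermal_neutral_zone <- function(animal, wind = 0.1, rh = 60,
                                 t_search = c(-40, 45)) {
  bmr <- animal$bmr_w
  f_uct <- function(t) {
    min(max_allowable_activity(animal, chamber_env(t, wind, rh))$q_max,
        1e6) - bmr
  }
  uct <- NA_real_
  if (f_uct(t_search[2]) > 0) {
    warning("no upper critical temperature below ", t_search[2], " deg C")
  } else {
    uct <- stats::uniroot(f_uct, t_search, tol = 0.01)$root
  }
  st <- animal_state(animal)
  f_lct <- function(t)
    required_q_gen(animal, chamber_env(t, wind, rh), st) - bmr
  hi <- if (is.na(uct)) t_search[2] else uct
  lct <- stats::uniroot(f_lct, c(t_search[1], hi), tol = 0.01)$root
  list(lct = lct, uct = uct)
}
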
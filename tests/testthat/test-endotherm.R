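# Steady-state heat-balance solver, thermoregulatory cascade, and the
# thermal neutral zone.

test_that("isothermal environment with no evaporation needs no heat", {
  an <- pika_animal(109, scale_fur_with_mass = FALSE)
  env <- env_state(t_air = an$core_temp, wind = 0.1,
                   suppress_evaporation = TRUE)
  sol <- solve_required_metabolic_rate(an, env, bmr_floor = FALSE)
  expect_equal(sol$q_gen, 0, tolerance = 1e-4)
})

test_that("bare lumped-conductance configuration matches the closed form", {
  # fur removed, radiation switched off, vasodilated: the chain reduces to
  # flesh conduction in series with forced convection at the skin
  an <- pika_animal(109, fur_density_cm2 = 0,
                    fur_length_dorsal_mm = 1e-3,
                    fur_length_ventral_mm = 1e-3,
                    flesh_conductivity = 2.8,
                    scale_fur_with_mass = FALSE,
                    config = list(emissivity = 1e-9,
                                  skin_evap_fraction = 0))
  t_air <- 0
  env <- env_state(t_air, wind = 3, suppress_evaporation = TRUE)
  sol <- solve_required_metabolic_rate(an, env, bmr_floor = FALSE)
  # independent series-resistance computation
  vol <- 0.109 / 1000
  b <- (3 * vol / (4 * pi * 2.25))^(1 / 3); a <- 2.25 * b
  e <- sqrt(1 - (b / a)^2)
  a_skin <- 2 * pi * b^2 * (1 + (a / b) * asin(e) / e)
  d <- vol^(1 / 3)
  re <- 3 * d / pikatherm:::air_kinematic_viscosity(t_air)
  nu <- 2 + 0.6 * sqrt(re) * 0.71^(1 / 3)
  h <- 0.9 * nu * pikatherm:::air_conductivity(t_air) / d
  k_tot <- 1 / (b / (2 * 2.8 * a_skin) + 1 / (h * a_skin * 0.8))
  expect_equal(sol$q_gen, k_tot * (40.1 - t_air), tolerance = 0.01)
})

test_that("every feasible solution closes the energy balance to 1 mW", {
  set.seed(11)
  an150 <- pika_animal(150); an109 <- chamber_animal()
  for (i in 1:25) {
    an <- if (i %% 2) an150 else an109
    env <- env_state(t_air = runif(1, -20, 30),
                     t_ground = runif(1, -20, 45),
                     t_sky = runif(1, -40, 25),
                     wind = runif(1, 0.05, 5),
                     rh = runif(1, 10, 95),
                     solar_dni = sample(c(0, 0, 400), 1),
                     solar_diffuse = runif(1, 0, 120))
    sol <- solve_required_metabolic_rate(an, env)
    if (sol$feasible) {
      resid <- sol$q_solar_abs + sol$q_ir_in + sol$q_gen -
        sol$q_ir_out - sol$q_conv - sol$q_evap_resp - sol$q_evap_skin
      expect_lt(abs(resid), 0.001)
      expect_gte(sol$q_gen, 0)
      expect_identical(sol$q_stored, 0)
    }
  }
})

test_that("the thermoregulatory cascade engages in order and holds BMR", {
  an <- chamber_animal()
  cold <- solve_required_metabolic_rate(an, chamber_env(0))
  expect_gt(cold$q_gen, an$bmr_w)
  expect_equal(cold$flesh_conductivity_used, an$flesh_conductivity)
  warm <- solve_required_metabolic_rate(an, chamber_env(21))
  expect_equal(warm$q_gen, an$bmr_w)
  expect_true(warm$posture_ratio_used > an$shape_ratio ||
              warm$flesh_conductivity_used > an$flesh_conductivity ||
              warm$core_temp_used > an$core_temp)
  hot <- solve_required_metabolic_rate(an, chamber_env(30))
  expect_false(hot$feasible)
  expect_equal(hot$core_temp_used, an$core_temp_max)
})

test_that("required rate falls and allowable multiple falls as air warms", {
  an <- chamber_animal()
  temps <- seq(-15, 18, by = 3)
  q <- vapply(temps, function(t)
    solve_required_metabolic_rate(an, chamber_env(t))$q_gen, numeric(1))
  expect_true(all(diff(q) <= 1e-6))
  mult <- vapply(seq(5, 35, by = 5), function(t)
    max_allowable_activity(an, chamber_env(t))$max_allowable_fmr_multiple,
    numeric(1))
  expect_true(all(diff(mult) <= 1e-6))
  # far below the TNZ the heat-dissipation limit never binds
  expect_gte(max_allowable_activity(an,
               chamber_env(-10))$max_allowable_fmr_multiple, 1.5)
})

test_that("TNZ detection agrees with a brute-force grid scan", {
  tz <- cached_tnz()
  expect_lt(tz$lct, tz$uct)
  an <- chamber_animal()
  grid <- seq(tz$uct - 1, tz$uct + 1, by = 0.01)
  q <- vapply(grid, function(t)
    max_allowable_activity(an, chamber_env(t))$q_max, numeric(1))
  uct_grid <- grid[which.min(abs(q - an$bmr_w))]
  expect_equal(tz$uct, uct_grid, tolerance = 0.02)
})

test_that("colder animals: smaller body pays more per gram; UCT falls with mass and fur", {
  q109 <- solve_required_metabolic_rate(chamber_animal(),
                                        chamber_env(-5))$q_gen / 109
  q150 <- solve_required_metabolic_rate(
    pika_animal(150, scale_fur_with_mass = FALSE), chamber_env(-5))$q_gen / 150
  expect_gt(q109, q150)
  # with mass-scaled fur, heavier animals exhaust heat dissipation sooner
  uct <- vapply(c(120, 150, 180), function(m)
    thermal_neutral_zone(pika_animal(m))$uct, numeric(1))
  expect_true(all(diff(uct) < 0))
  # and longer fur lowers the UCT at fixed mass
  expect_lt(thermal_neutral_zone(pika_animal(150, fur_scale = 1.2))$uct,
            uct[2])
})

test_that("core temperature and posture effects sit in the reported bands", {
  an <- chamber_animal()
  eff <- vapply(c(-15, 0, 14), function(t) {
    sw <- list(list(parameter = "core_temp", low = 38, high = 43,
                    t_air = t, metric = "W_g"))
    sensitivity_table(an, sw)$percent_change
  }, numeric(1))
  expect_true(all(eff >= 8 & eff <= 25))
  a150 <- pika_animal(150)
  post <- vapply(c(-15, 0, 15), function(t) {
    sw <- list(list(parameter = "shape_ratio", low = 1.5, high = 3.0,
                    t_air = t))
    sensitivity_table(a150, sw)$percent_change
  }, numeric(1))
  expect_true(mean(post) >= 5 && mean(post) <= 15)
})

test_that("reflective pelts under overhead sun must burn more fuel", {
  an <- chamber_animal()
  sw <- list(list(parameter = "fur_reflectivity", low = 0.15, high = 0.90,
                  t_air = 0,
                  env = env_state(0, wind = 0.1, solar_dni = 500,
                                  solar_elevation = 90)))
  pc <- sensitivity_table(an, sw)$percent_change
  expect_gt(pc, 5)
  expect_lt(pc, 35)
})
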
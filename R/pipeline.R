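# End-to-end reproduction suite: runs the chamber validation, TNZ
# detection, sensitivity analyses, activity budgets and warming scenario
# from scratch and tabulates the headline quantities.

#' Run the full reproduction suite
#'
#' Executes, from scratch: the 109 g chamber validation (TNZ plateau and
#' upper critical temperature), the summer/winter pelage TNZ shift, the
#' fur-density / O2-extraction / flesh-conductivity sensitivities, the
#' microclimate wind sensitivity at animal height, the field
#' activity-threshold sweep, and the July 1500 m activity budgets
#' (120 g summer baseline and +5 deg C, 150 g winter baseline).  Each
#' stage that fails is recorded with an `NA` value and the error message;
#' the suite continues.
#'
#' @param seed Integer seed (consumed for API stability; every stage is
#'   deterministic).
#' @param site A [pika_site()]; default the standard GNP field site.
#' @return data.frame with columns `quantity`, `description`, `value`,
#'   `n` (problem size), `units`, `error`.
#' @export
run_reproduction_suite <- function(seed = 1, site = pika_site()) {
  set.seed(seed)
  rows <- list()
  add <- function(quantity, description, units, n, expr) {
    val <- NA_real_; err <- NA_character_
    tryCatch(val <- expr(), error = function(e) err <<- conditionMessage(e))
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, description = description, value = val,
      n = n, units = units, error = err)
  }

  a109 <- chamber_animal()
  a109w <- chamber_animal(pelage = "winter")

  add("chamber_plateau", "TNZ-plateau metabolic rate, 109 g chamber pika",
      "W", 24, function() {
    simulate_chamber_curve(a109, seq(-15, 22, by = 2))$plateau_W
  })
  tz <- NULL
  add("upper_critical_temp", "UCT (FMR = BMR) of the 109 g chamber pika",
      "degC", 1, function() {
    tz <<- thermal_neutral_zone(a109); tz$uct
  })
  add("pelage_tnz_shift", "Summer-vs-winter shift of the TNZ upper bound",
      "degC", 2, function() {
    uct_s <- if (!is.null(tz)) tz$uct else thermal_neutral_zone(a109)$uct
    uct_s - thermal_neutral_zone(a109w)$uct
  })
  add("field_threshold", "Air temperature where a 150 g summer pika's max FMR/BMR = 1.5",
      "degC", 1, function() {
    field_activity_threshold(pika_animal(150))
  })
  add("fur_density_reduction",
      "Percent reduction in 0 degC chamber rate, fur 250 -> 3000 hairs/cm2",
      "%", 2, function() {
    sw <- list(list(parameter = "fur_density_cm2", low = 250, high = 3000,
                    t_air = 0))
    -sensitivity_table(a109, sw)$percent_change
  })
  add("o2_extraction_reduction",
      "Max percent reduction in rate, O2 extraction 5 -> 30%",
      "%", 7, function() {
    max(vapply(seq(-15, 15, by = 5), function(t) {
      sw <- list(list(parameter = "o2_extraction", low = 5, high = 30,
                      t_air = t))
      -sensitivity_table(a109, sw)$percent_change
    }, numeric(1)))
  })
  add("flesh_conductivity_increase",
      "Max percent increase in rate, flesh conductivity 0.5 -> 2.8 W/mK",
      "%", 7, function() {
    max(vapply(seq(-15, 15, by = 5), function(t) {
      sw <- list(list(parameter = "flesh_conductivity", low = 0.5,
                      high = 2.8, t_air = t))
      sensitivity_table(a109, sw)$percent_change
    }, numeric(1)))
  })
  add("wind_cooling_pct",
      "Max percent decrease in animal-height air temperature, wind 0.1 -> 1.5 m/s",
      "%", 24, function() {
    w <- gnp_weather(7, elevation = site$elevation)
    m1 <- microclimate_day(site, w, 7, wind_animal = 0.1)
    m2 <- microclimate_day(site, w, 7, wind_animal = 1.5)
    max(100 * (m1$t_air_animal_C - m2$t_air_animal_C) / m1$t_air_animal_C)
  })

  b120 <- b120_5 <- NULL
  add("july_allowable_hours_120g",
      "Allowable above-talus hours, 120 g summer pika, July 1500 m baseline",
      "h", 21, function() {
    b120 <<- daily_activity_budget(pika_animal(120), site, month = 7)
    b120$allowable_hours
  })
  add("warming_decline_120g_pct",
      "Percent decline in allowable hours under +5 degC, 120 g summer, July 1500 m",
      "%", 21, function() {
    b120_5 <<- daily_activity_budget(pika_animal(120), site, month = 7,
                                     warming_delta = 5)
    b <- if (!is.null(b120)) b120 else
      daily_activity_budget(pika_animal(120), site, month = 7)
    -warming_scenario_comparison(list(k = b),
                                 list(k = b120_5))$change_vs_baseline_pct
  })
  add("restriction_150g_winter_pct",
      "Percent restriction of allowable hours, 150 g winter pika, July 1500 m",
      "%", 21, function() {
    daily_activity_budget(pika_animal(150, pelage = "winter"), site,
                          month = 7)$restriction_pct
  })

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
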
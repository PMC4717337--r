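# Seeded synthetic-data generators: logger networks, behaviour-observation
# sessions, and chamber measurement envelopes.  One generator module owns
# all randomness; the analysis functions are deterministic given inputs.
# Every generator attaches its truth as the "truth" attribute so recovery
# tests are self-checking.

#' Logger-network generator configuration
#'
#' Defaults emulate the seven-site 2008 deployment: elevations spread
#' over 1512-2274 m, 15-min cadence, a diurnal sinusoid on an imposed
#' linear lapse rate, an unshaded above-talus midday solar bump, and a
#' damped, lagged below-talus companion series.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_sites Number of sites.
#' @param elevation_range m, `c(low, high)`.
#' @param true_lapse_rate Imposed lapse rate, deg C/km.
#' @param base_mean_C Daily mean temperature at the lowest site.
#' @param diurnal_amplitude_C Half-range of the diurnal sinusoid.
#' @param solar_bump_C Extra midday heating of the unshaded above-talus
#'   logger.
#' @param noise_sd_C Gaussian measurement/weather noise SD.
#' @param damping Below-talus amplitude ratio (relative to the above
#'   series without the solar bump).
#' @param lag_h Below-talus phase lag, hours.
#' @param below_warm_bias_C Warm offset of the below-talus mean relative
#'   to the shaded diurnal mean (interstices are buffered toward the
#'   solar-heated surface's daily mean).
#' @param cadence_min Sampling interval, minutes.
#' @param n_days Days of record.
#' @param start Start timestamp (POSIXct, UTC).
#' @return Named list of class `logger_config`.
#' @export
logger_config <- function(seed = 1, n_sites = 7,
                          elevation_range = c(1512, 2274),
                          true_lapse_rate = -9.46, base_mean_C = 12,
                          diurnal_amplitude_C = 8, solar_bump_C = 10,
                          noise_sd_C = 0.8, damping = 0.12, lag_h = 10,
                          below_warm_bias_C = 1.5,
                          cadence_min = 15, n_days = 7,
                          start = as.POSIXct("2008-07-28 00:00:00",
                                             tz = "UTC")) {
  stopifnot(noise_sd_C >= 0, n_sites >= 1, damping >= 0, damping <= 1)
  structure(as.list(environment()), class = "logger_config")
}

#' Generate a synthetic logger network
#'
#' Per site, an above-talus series (diurnal sinusoid peaking at 14:00
#' plus a midday solar bump and noise on the lapse-adjusted mean) and a
#' below-talus companion (damped, lagged, no solar bump).
#'
#' @param config A [logger_config()].
#' @return data.frame in the logger CSV dialect: `site_id`,
#'   `elevation_m`, `placement` ("above"/"below"), `timestamp`, `temp_C`,
#'   `rh_pct`; attribute `truth` carries the generator parameters.
#' @export
gen_logger_network <- function(config = logger_config()) {
  set.seed(config$seed)
  elevs <- round(seq(config$elevation_range[1], config$elevation_range[2],
                     length.out = config$n_sites))
  step_s <- config$cadence_min * 60
  times <- config$start + seq(0, config$n_days * 86400 - step_s, by = step_s)
  hours <- as.numeric(difftime(times, trunc(times, "days"),
                               units = "hours"))
  out <- list()
  for (i in seq_len(config$n_sites)) {
    mean_i <- config$base_mean_C + config$true_lapse_rate *
      (elevs[i] - config$elevation_range[1]) / 1000
    diurnal <- config$diurnal_amplitude_C *
      sin(2 * pi * (hours - 9) / 24)
    bump <- config$solar_bump_C *
      pmax(0, sin(pi * (hours - 10) / 8)) * (hours >= 10 & hours <= 18)
    above <- mean_i + diurnal + bump +
      stats::rnorm(length(times), 0, config$noise_sd_C)
    diurnal_lag <- config$diurnal_amplitude_C * config$damping *
      sin(2 * pi * (hours - 9 - config$lag_h) / 24)
    below <- mean_i + config$below_warm_bias_C + diurnal_lag +
      stats::rnorm(length(times), 0, config$noise_sd_C / 2)
    out[[length(out) + 1]] <- data.frame(
      site_id = sprintf("S%02d", i), elevation_m = elevs[i],
      placement = "above", timestamp = times, temp_C = above,
      rh_pct = 55)
    out[[length(out) + 1]] <- data.frame(
      site_id = sprintf("S%02d", i), elevation_m = elevs[i],
      placement = "below", timestamp = times, temp_C = below,
      rh_pct = 70)
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- config
  res
}

#' Behaviour-dataset generator configuration
#'
#' Defaults emulate the 8-site x 12-session design (3 windows x 4 dates,
#' n = 96) with log-linear covariate effects on per-capita activity:
#' more activity at high elevation and on north-facing slopes, less when
#' minimum above-talus temperature is high, and a negative elevation x
#' aspect interaction.  Effect sizes default to the field estimates.
#'
#' @param seed Integer seed.
#' @param n_sites,n_dates Sites and dates per window.
#' @param beta_e,beta_a,beta_t,beta_ea Log-linear effects on `ln(e)`,
#'   `ln(a)` (northness), `ln(t)` and the interaction.
#' @param mean_events Expected per-capita events at average covariates.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersion); `Inf` gives Poisson, and `gaussian = TRUE` switches
#'   to a log-normal response emulation.
#' @param suppression_above_20 Multiplier on non-haying event means when
#'   tmin >= 20 deg C (behavioural shutdown beyond the covariate trend).
#' @param calls_base,calls_midday_effect,calls_temp_slope,calls_noise_sd
#'   Calls-per-occupant model: base level, midday contrast, slope per
#'   deg C, residual SD.
#' @param gaussian Use a Gaussian-on-log-response generator instead of
#'   negative-binomial counts.
#' @return Named list of class `behavior_config`.
#' @export
behavior_config <- function(seed = 1, n_sites = 8, n_dates = 4,
                            beta_e = 0.36, beta_a = 0.96, beta_t = -0.76,
                            beta_ea = -0.35, mean_events = 18,
                            dispersion = 8, suppression_above_20 = 0.45,
                            calls_base = 32, calls_midday_effect = -14.7,
                            calls_temp_slope = -0.5, calls_noise_sd = 6,
                            gaussian = FALSE) {
  structure(as.list(environment()), class = "behavior_config")
}

#' Generate a synthetic behaviour-observation dataset
#'
#' @param config A [behavior_config()].
#' @return Session data.frame (one row per site x window x date) in the
#'   session CSV dialect: `site_id`, `date`, `window`, `elevation_m`,
#'   `aspect_deg`, `occupants`, behaviour counts, `calls`,
#'   `tmin_above_C`; attribute `truth` carries the generator parameters.
#' @export
gen_behavior_dataset <- function(config = behavior_config()) {
  set.seed(config$seed)
  n_sites <- config$n_sites
  elevs <- round(seq(1500, 2300, length.out = n_sites))
  aspects <- seq(0, 315, length.out = n_sites)
  windows <- c("morning", "midday", "evening")
  dates <- as.Date("2009-07-15") + seq_len(config$n_dates) - 1
  design <- expand.grid(site = seq_len(n_sites), window = windows,
                        date = dates, stringsAsFactors = FALSE)
  elevation <- elevs[design$site]
  aspect <- aspects[design$site]
  # session minimum above-talus temperature: window level + lapse + noise
  t_base <- c(morning = 8, midday = 22, evening = 13)[design$window]
  tmin <- t_base - 8 * (elevation - 1500) / 1000 +
    stats::rnorm(nrow(design), 0, 2.5)
  tmin <- pmax(tmin, 1)
  ln_e <- log(elevation); ln_a <- log(northness_index(aspect))
  ln_t <- log(tmin)
  lp <- config$beta_e * ln_e + config$beta_a * ln_a +
    config$beta_t * ln_t + config$beta_ea * ln_e * ln_a
  lp_haying <- lp - config$beta_t * ln_t  # haying is temperature-indifferent
  b0 <- log(config$mean_events) - mean(lp)
  occupants <- 1 + stats::rpois(nrow(design), 2.5)
  mu_pc <- exp(b0 + lp)                       # per-capita mean events
  # category composition; haying is temperature-indifferent
  shares <- c(haying = 0.12, foraging = 0.33, moving_fast = 0.12,
              moving_slow = 0.18, vigilant = 0.25)
  hot <- tmin >= 20
  mu_pc_haying <- exp(b0 + lp_haying)
  counts <- sapply(names(shares), function(cat) {
    mu <- if (cat == "haying") mu_pc_haying * occupants * shares[[cat]]
          else mu_pc * occupants * shares[[cat]] *
            ifelse(hot, config$suppression_above_20, 1)
    if (config$gaussian) {
      pmax(0, round(stats::rnorm(length(mu), mu, sqrt(mu) + 0.5)))
    } else if (is.infinite(config$dispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
    }
  })
  cpo <- config$calls_base + config$calls_midday_effect *
    (design$window == "midday") + config$calls_temp_slope * tmin +
    stats::rnorm(nrow(design), 0, config$calls_noise_sd)
  calls <- pmax(0, round(cpo * occupants))
  out <- data.frame(site_id = sprintf("B%02d", design$site),
                    date = design$date, window = design$window,
                    elevation_m = elevation, aspect_deg = aspect,
                    occupants = occupants, counts, calls = calls,
                    tmin_above_C = round(tmin, 1))
  attr(out, "truth") <- config
  out
}

#' Chamber-envelope generator configuration
#'
#' @param seed Integer seed.
#' @param bmr_w Plateau (thermoneutral) metabolic rate, W.
#' @param lct_C,uct_C Thermal-neutral-zone bounds of the emulated
#'   empirical envelope.
#' @param cold_slope_w_per_C Below-LCT slope (whole-animal thermal
#'   conductance scale), W per deg C.
#' @param noise_sd_w Measurement noise SD, W.
#' @param halfwidth_frac Relative half-width of the empirical envelope
#'   band.
#' @param t_grid Measurement temperatures, deg C.
#' @return Named list of class `chamber_config`.
#' @export
chamber_config <- function(seed = 1, bmr_w = 0.923, lct_C = 17.5,
                           uct_C = 24, cold_slope_w_per_C = 0.037,
                           noise_sd_w = 0.04, halfwidth_frac = 0.15,
                           t_grid = seq(-15, 24, by = 1)) {
  structure(as.list(environment()), class = "chamber_config")
}

scholander_curve <- function(t, bmr, lct, slope) {
  bmr + slope * pmax(0, lct - t)
}

#' Generate a noisy chamber measurement envelope
#'
#' Piecewise-linear Scholander-type curve (linear rise below the LCT,
#' plateau at BMR through the TNZ) with Gaussian noise, plus the
#' noise-free envelope band used for curve-bracketing checks.
#'
#' @param config A [chamber_config()].
#' @return data.frame `t_air`, `q_gen_W` (noisy), `band_low`, `band_high`
#'   (noise-free envelope); attribute `truth`.
#' @export
gen_chamber_envelope <- function(config = chamber_config()) {
  set.seed(config$seed)
  t <- config$t_grid[config$t_grid <= config$uct_C]
  centre <- scholander_curve(t, config$bmr_w, config$lct_C,
                             config$cold_slope_w_per_C)
  noisy <- centre + stats::rnorm(length(t), 0, config$noise_sd_w)
  out <- data.frame(t_air = t, q_gen_W = noisy,
                    band_low = centre * (1 - config$halfwidth_frac),
                    band_high = centre * (1 + config$halfwidth_frac))
  attr(out, "truth") <- config
  out
}

#' Fit a Scholander curve and detect the thermal neutral zone
#'
#' Grid-searches the LCT over the measured temperatures, fitting a
#' plateau (mean of points above the breakpoint) and a cold-side line
#' pinned to the plateau at the breakpoint, and picks the breakpoint
#' minimising the residual sum of squares.  The UCT is the highest
#' measured temperature (the envelope ends where the animal overheats).
#'
#' @param points data.frame with `t_air` and `q_gen_W`.
#' @return List: `lct`, `uct`, `plateau_W`, `cold_slope_w_per_C`, `rss`.
#' @export
fit_scholander <- function(points) {
  t <- points$t_air; q <- points$q_gen_W
  cands <- sort(unique(t))
  cands <- cands[cands > min(t) & cands < max(t)]
  best <- NULL
  for (lct in cands) {
    warm <- t >= lct
    if (sum(warm) < 2 || sum(!warm) < 2) next
    plateau <- mean(q[warm])
    x <- lct - t[!warm]
    slope <- sum(x * (q[!warm] - plateau)) / sum(x^2)
    resid <- c(q[warm] - plateau,
               q[!warm] - (plateau + slope * x))
    rss <- sum(resid^2)
    if (is.null(best) || rss < best$rss)
      best <- list(lct = lct, uct = max(t), plateau_W = plateau,
                   cold_slope_w_per_C = slope, rss = rss)
  }
  if (is.null(best)) stop("too few points to fit a Scholander curve",
                          call. = FALSE)
  best
}
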
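# Hourly microclimate: diurnal air temperature, lapse-rate adjustment,
# wind profiles, substrate heat conduction, and the coupled surface energy
# balance that produces animal-height conditions.

#' Apply an altitudinal lapse rate
#'
#' @param temperature Temperature(s) at the reference elevation, deg C.
#' @param delta_elevation Elevation change in metres (positive upward).
#' @param lapse_rate deg C per km; negative cools with ascent.
#' @return Adjusted temperature(s), deg C.
#' @export
apply_lapse_rate <- function(temperature, delta_elevation, lapse_rate) {
  assert_finite(temperature); assert_finite(delta_elevation)
  assert_finite(lapse_rate)
  temperature + lapse_rate * delta_elevation / 1000
}

#' Continuous diurnal air-temperature curve
#'
#' Returns a function of local solar hour. Daytime follows a sine with the
#' minimum at sunrise and the maximum `peak_offset` hours after solar noon;
#' night-time decays exponentially from the sunset value, renormalised to
#' land exactly on `t_min` at the next sunrise.
#'
#' @param weather A [daily_weather()].
#' @param sun A [sun_events()] list (sunrise/noon/sunset).
#' @param peak_offset Hours after solar noon of the daily maximum.
#' @param night_decay Dimensionless exponential decay rate over the night.
#' @return `function(hour)` returning deg C; vectorised over hour.
#' @export
diurnal_temperature_fn <- function(weather, sun, peak_offset = 1,
                                   night_decay = 2.5) {
  t_min <- weather$t_min; t_max <- weather$t_max
  assert_finite(c(t_min, t_max))
  rise <- sun$sunrise; set <- sun$sunset
  if (!is.finite(rise) || !is.finite(set)) { rise <- 6; set <- 18 }
  t_peak <- sun$noon + peak_offset
  # day sine: argument pi/2 at t_peak, 0 at sunrise
  half <- t_peak - rise
  t_set_val <- t_min + (t_max - t_min) *
    max(0, sin(pi / 2 * (set - rise) / half))
  night_len <- 24 - (set - rise)
  function(hour) {
    h <- hour %% 24
    vapply(h, function(hh) {
      if (t_max == t_min) return(t_min)
      if (hh >= rise && hh <= set) {
        x <- (hh - rise) / half
        if (x <= 2) t_min + (t_max - t_min) * sin(pi / 2 * x)
        else t_min   # pathological geometry (peak before mid-day)
      } else {
        s <- if (hh > set) (hh - set) / night_len else (hh + 24 - set) / night_len
        t_min + (t_set_val - t_min) *
          (exp(-night_decay * s) - exp(-night_decay)) / (1 - exp(-night_decay))
      }
    }, numeric(1))
  }
}

#' Hourly diurnal air temperatures
#'
#' @inheritParams diurnal_temperature_fn
#' @return Numeric vector of 24 temperatures at hours 0-23.
#' @export
diurnal_air_temperature <- function(weather, sun, peak_offset = 1,
                                    night_decay = 2.5) {
  fn <- diurnal_temperature_fn(weather, sun, peak_offset, night_decay)
  fn(0:23)
}

#' Wind speed at a different height (logarithmic profile)
#'
#' @param reference_wind Wind speed at `reference_height`, m/s.
#' @param reference_height,target_height Heights above ground, m.
#' @param roughness Aerodynamic roughness length, m.
#' @return Wind speed at `target_height`, m/s.
#' @export
wind_at_height <- function(reference_wind, reference_height, target_height,
                           roughness = 0.01) {
  stopifnot(roughness > 0, reference_height > roughness)
  if (any(target_height <= roughness))
    stop("target_height must exceed the roughness length", call. = FALSE)
  reference_wind * log(target_height / roughness) /
    log(reference_height / roughness)
}

# Diurnal wind schedule at pika height: low overnight, sinusoidal daytime
# peak in mid-afternoon (the field convention 0.1-4.0 m/s).
diurnal_wind_fn <- function(weather, sun) {
  wmin <- weather$wind_min; wmax <- weather$wind_max
  rise <- if (is.finite(sun$sunrise)) sun$sunrise else 6
  set <- if (is.finite(sun$sunset)) sun$sunset else 18
  peak <- sun$noon + 2
  half <- peak - rise
  function(hour) {
    h <- hour %% 24
    day <- h >= rise & h <= set
    x <- pmin((h - rise) / half, 2)
    w <- wmin + (wmax - wmin) * pmax(0, sin(pi / 2 * x))
    ifelse(day, w, wmin)
  }
}

# Build a substrate depth grid: geometric spacing from the surface to at
# least `max_depth`, with every requested output depth inserted as a node.
substrate_grid <- function(depths = numeric(), dz0 = 0.01, ratio = 1.35,
                           max_depth = 1.0) {
  z <- 0; dz <- dz0
  while (z[length(z)] < max_depth) {
    z <- c(z, z[length(z)] + dz)
    dz <- dz * ratio
  }
  # drop auto nodes crowding an explicitly requested depth (keeps the
  # minimum spacing, and thus the stable time step, near dz0)
  for (d in depths) {
    near <- abs(z - d) < 0.35 * dz0 * ratio^findInterval(d, z)
    z <- z[!near | z == 0]
  }
  sort(unique(signif(c(z, depths), 10)))
}

#' Periodic substrate temperature profile under a surface-temperature forcing
#'
#' Explicit finite differences on a geometric depth grid with a zero-flux
#' deep boundary; the forcing day is repeated until the solution is
#' periodic (max hourly change between successive days < `tol` deg C).
#'
#' @param site A [pika_site()] (supplies thermal properties).
#' @param surface_forcing 24 hourly surface temperatures (deg C), treated
#'   as a periodic day; linearly interpolated between hours.
#' @param depths Output depths, m (positive downward).
#' @param tol Convergence tolerance, deg C.
#' @param max_days Spin-up cap; exceeding it without convergence is an error
#'   (the solver never silently clips a diverging solution).
#' @return Matrix 24 x length(depths): hourly temperatures at each depth;
#'   attributes `days` (spin-up used) and `grid`.
#' @export
substrate_temperature_profile <- function(site, surface_forcing, depths,
                                          tol = 0.01, max_days = 60) {
  stopifnot(length(surface_forcing) == 24)
  assert_finite(surface_forcing)
  k <- site$substrate_conductivity
  alpha <- k / (site$substrate_density * site$substrate_specific_heat)
  z <- substrate_grid(depths)
  n <- length(z)
  dzmin <- min(diff(z))
  dt <- 0.5 * dzmin^2 / (2 * alpha)
  steps <- ceiling(86400 / dt); dt <- 86400 / steps
  if (!is.finite(dt) || dt <= 0) stop("conduction solver: bad time step")

  force_at <- function(tt) {  # tt in hours, periodic linear interpolation
    h0 <- floor(tt) %% 24; h1 <- (h0 + 1) %% 24; w <- tt - floor(tt)
    (1 - w) * surface_forcing[h0 + 1] + w * surface_forcing[h1 + 1]
  }

  temp <- rep(mean(surface_forcing), n)
  hourly_prev <- matrix(NA_real_, 24, n)
  up <- diff(z)            # spacing below node i is up[i]
  for (day in seq_len(max_days)) {
    hourly <- matrix(NA_real_, 24, n)
    for (s in seq_len(steps)) {
      tt <- (s - 1) * dt / 3600
      temp[1] <- force_at(tt)
      lap <- numeric(n)
      i <- 2:(n - 1)
      lap[i] <- 2 * ((temp[i + 1] - temp[i]) / up[i] -
                     (temp[i] - temp[i - 1]) / up[i - 1]) / (up[i] + up[i - 1])
      lap[n] <- 2 * (temp[n - 1] - temp[n]) / up[n - 1]^2  # zero-flux bottom
      temp <- temp + alpha * dt * lap
      temp[1] <- force_at(s * dt / 3600)
      if (any(!is.finite(temp)))
        stop("conduction solver diverged (CFL violation)", call. = FALSE)
      hr <- s * dt / 3600
      if (abs(hr - round(hr)) < dt / 7200 && round(hr) >= 1 && round(hr) <= 24)
        hourly[(round(hr) - 1) %% 24 + 1, ] <- temp
    }
    if (day > 1 && max(abs(hourly - hourly_prev)) < tol) {
      out <- sapply(depths, function(d) {
        j <- findInterval(d, z)
        if (z[j] == d) hourly[, j]
        else {
          w <- (d - z[j]) / (z[j + 1] - z[j])
          (1 - w) * hourly[, j] + w * hourly[, j + 1]
        }
      })
      out <- matrix(out, nrow = 24, dimnames = list(NULL, paste0("z", depths)))
      return(structure(out, days = day, grid = z))
    }
    hourly_prev <- hourly
  }
  stop("conduction solver failed to reach a periodic state within ",
       max_days, " days", call. = FALSE)
}

# Ground-surface convective coefficient (W/m^2 K) from wind at ~1 m; the
# floor reflects vigorous free convection over a heated rough talus
# surface in near-calm air.
ground_h_conv <- function(wind_1m) {
  pmax(11.5, 6.2 + 4.2 * wind_1m^0.8)
}

# Clear and cloudy sky downwelling IR (W/m^2); Swinbank clear-sky
# emissivity with a linear cloud correction.
sky_ir_down <- function(t_air_c, cloud_frac) {
  tk <- c_to_k(t_air_c)
  eps_clear <- min(1, 9.365e-6 * tk^2)
  eps <- eps_clear * (1 - 0.84 * cloud_frac) + 0.84 * cloud_frac
  eps * SIGMA_SB * tk^4
}

#' Simulate the hourly microclimate of one representative day
#'
#' Couples the diurnal air-temperature curve, clear-sky solar on the slope,
#' a massless-surface energy balance, and the substrate conduction column,
#' spun up to a periodic day.  Animal-height air temperature interpolates
#' the log-profile between the surface and the reference height.
#'
#' @param site A [pika_site()].
#' @param weather A [daily_weather()]; extremes are lapse-adjusted from
#'   `weather$reference_elevation` to `site$elevation`.
#' @param month Month 1-12 (sets the solar day; mid-month).
#' @param shade If TRUE the surface receives no direct beam (shaded
#'   above-talus microsite); the substrate column is driven by this shaded
#'   balance, matching below-talus interstices.
#' @param wind_animal Optional constant wind (m/s) at animal height
#'   overriding the diurnal 0.1-4.0 schedule.
#' @param lapse_rate deg C/km for the elevation adjustment.
#' @param tol,max_days Periodic-convergence controls for the substrate.
#' @return data.frame with one row per hour 0-23: `hour`, `t_air_ref_C`,
#'   `t_air_animal_C`, `t_surface_C`, `t_sub_<depth>cm_C` columns,
#'   `wind_animal_ms`, `rh_pct`, `solar_direct_Wm2`, `solar_diffuse_Wm2`,
#'   `sky_ir_down_Wm2`, `sun_up`, `twilight`, `eb_residual_Wm2`.
#' @export
microclimate_day <- function(site, weather, month, shade = FALSE,
                             wind_animal = NULL, lapse_rate = -8,
                             tol = 0.01, max_days = 40) {
  doy <- mid_month_doy(month)
  sun <- sun_events(site$latitude, doy)
  d_elev <- site$elevation - weather$reference_elevation
  w_adj <- weather
  w_adj$t_min <- apply_lapse_rate(weather$t_min, d_elev, lapse_rate)
  w_adj$t_max <- apply_lapse_rate(weather$t_max, d_elev, lapse_rate)
  t_air_fn <- diurnal_temperature_fn(w_adj, sun)
  wind_fn <- if (is.null(wind_animal)) diurnal_wind_fn(w_adj, sun)
             else function(h) rep(wind_animal, length(h))

  z0 <- site$roughness_length
  z_ref <- site$reference_height
  z_anim <- site$animal_height
  w_interp <- log(z_anim / z0) / log(z_ref / z0)  # weight toward reference

  k <- site$substrate_conductivity
  alpha <- k / (site$substrate_density * site$substrate_specific_heat)
  depths <- site$refuge_depths
  z <- substrate_grid(depths)
  n <- length(z); up <- diff(z)
  dzmin <- min(up)
  dt <- 0.5 * dzmin^2 / (2 * alpha)
  steps <- ceiling(86400 / dt); dt <- 86400 / steps
  cloud_frac <- weather$cloud_cover / 100
  alb <- site$substrate_reflectivity
  eps_g <- 0.95

  # precompute per-substep forcing
  tt <- (seq_len(steps) - 1) * dt / 3600
  t_air_sub <- t_air_fn(tt)
  wind_anim_sub <- wind_fn(tt)
  wind_1m_sub <- wind_at_height(wind_anim_sub, z_anim, 1.0, z0)
  sol <- lapply(tt, function(h)
    solar_on_slope(site, doy, h, weather$cloud_cover))
  s_dir_sub <- vapply(sol, `[[`, numeric(1), "solar_direct")
  s_dif_sub <- vapply(sol, `[[`, numeric(1), "solar_diffuse")
  if (shade) s_dir_sub[] <- 0
  ir_down_sub <- vapply(t_air_sub, sky_ir_down, numeric(1), cloud_frac)
  h_conv_sub <- ground_h_conv(wind_1m_sub)

  solve_surface <- function(ts_guess, t1, dz1, s_abs, ir_dn, h_c, t_air) {
    ts <- ts_guess
    for (it in 1:6) {
      tk <- c_to_k(ts)
      f <- s_abs + eps_g * ir_dn - eps_g * SIGMA_SB * tk^4 -
        h_c * (ts - t_air) - k * (ts - t1) / dz1
      df <- -4 * eps_g * SIGMA_SB * tk^3 - h_c - k / dz1
      ts <- ts - f / df
    }
    ts
  }

  temp <- rep(mean(c(w_adj$t_min, w_adj$t_max)), n)
  hourly_prev <- NULL
  mark_step <- vapply(0:23, function(h) which.min(abs(tt - h)), integer(1))
  shallow <- z <= 0.5  # convergence judged on the diurnally active zone

  for (day in seq_len(max_days)) {
    hourly <- matrix(NA_real_, 24, n)
    resid <- numeric(24)
    for (s in seq_len(steps)) {
      s_abs <- (1 - alb) * (s_dir_sub[s] + s_dif_sub[s])
      temp[1] <- solve_surface(temp[1], temp[2], up[1], s_abs,
                               ir_down_sub[s], h_conv_sub[s], t_air_sub[s])
      lap <- numeric(n)
      i <- 2:(n - 1)
      lap[i] <- 2 * ((temp[i + 1] - temp[i]) / up[i] -
                     (temp[i] - temp[i - 1]) / up[i - 1]) / (up[i] + up[i - 1])
      lap[n] <- 2 * (temp[n - 1] - temp[n]) / up[n - 1]^2
      temp[-1] <- temp[-1] + alpha * dt * lap[-1]
      if (any(!is.finite(temp)))
        stop("surface-coupled conduction diverged (CFL violation)",
             call. = FALSE)
      hit <- which(mark_step == s)
      if (length(hit)) {
        # re-balance the massless surface against the freshly updated
        # subsurface before reporting, so the recorded state closes the
        # surface energy budget
        temp[1] <- solve_surface(temp[1], temp[2], up[1], s_abs,
                                 ir_down_sub[s], h_conv_sub[s], t_air_sub[s])
        hourly[hit, ] <- rep(temp, each = length(hit))
        tk <- c_to_k(temp[1])
        resid[hit] <- s_abs + eps_g * ir_down_sub[s] -
          eps_g * SIGMA_SB * tk^4 - h_conv_sub[s] * (temp[1] - t_air_sub[s]) -
          k * (temp[1] - temp[2]) / up[1]
      }
    }
    if (day == 1) {
      # re-anchor the whole column at the first-day surface mean so the
      # deep (slow) nodes start at the right level
      temp[] <- mean(hourly[, 1])
    } else if (!is.null(hourly_prev) &&
               max(abs(hourly[, shallow] - hourly_prev[, shallow])) < tol) {
      break
    }
    hourly_prev <- hourly
    if (day == max_days)
      stop("microclimate failed to reach a periodic state", call. = FALSE)
  }

  hrs <- 0:23
  t_ref <- t_air_sub[mark_step]
  t_surf <- hourly[, 1]
  t_anim <- t_surf + (t_ref - t_surf) * w_interp
  sub_cols <- sapply(depths, function(d) {
    j <- findInterval(d, z)
    if (z[j] == d) hourly[, j]
    else {
      w <- (d - z[j]) / (z[j + 1] - z[j])
      (1 - w) * hourly[, j] + w * hourly[, j + 1]
    }
  })
  sub_cols <- matrix(sub_cols, nrow = 24)
  colnames(sub_cols) <- paste0("t_sub_", round(depths * 100), "cm_C")

  out <- data.frame(
    hour = hrs, t_air_ref_C = t_ref, t_air_animal_C = t_anim,
    t_surface_C = t_surf, sub_cols,
    wind_animal_ms = wind_anim_sub[mark_step], rh_pct = weather$rh,
    solar_direct_Wm2 = s_dir_sub[mark_step],
    solar_diffuse_Wm2 = s_dif_sub[mark_step],
    sky_ir_down_Wm2 = ir_down_sub[mark_step],
    sun_up = vapply(hrs, function(h)
      solar_elevation(site$latitude, doy, h) > 0, logical(1)),
    twilight = vapply(hrs, function(h) {
      el <- solar_elevation(site$latitude, doy, h); el <= 0 && el > -16
    }, logical(1)),
    eb_residual_Wm2 = resid, check.names = FALSE)
  attr(out, "spinup_days") <- day
  attr(out, "weather_adjusted") <- w_adj
  attr(out, "month") <- month
  out
}
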
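# Lapse-rate estimation, consistency filtering and refuge offsets.

mk_loggers <- function(slopes_truth, elevs, temps = NULL,
                       instant = as.POSIXct("2008-08-04 14:00:00",
                                            tz = "UTC")) {
  if (is.null(temps)) temps <- 20 + slopes_truth * (elevs - 1500) / 1000
  do.call(rbind, lapply(seq_along(elevs), function(i) {
    data.frame(site_id = paste0("L", i), elevation_m = elevs[i],
               timestamp = instant, temp_C = temps[i], rh_pct = 60)
  }))
}

test_that("perfectly linear data recover the imposed slope with R2 = 1", {
  elevs <- seq(1512, 2274, length.out = 7)
  d <- mk_loggers(-9.46, elevs)
  e <- estimate_lapse_rate(d, d$timestamp[1])
  expect_equal(e$slope, -9.46, tolerance = 1e-9)
  expect_equal(e$r_squared, 1, tolerance = 1e-9)
  expect_true(e$consistent)
})

test_that("identical temperatures give slope 0; degenerate inputs error", {
  elevs <- c(1500, 1800, 2100)
  d <- mk_loggers(0, elevs, temps = rep(12, 3))
  e <- estimate_lapse_rate(d, d$timestamp[1])
  expect_equal(e$slope, 0, tolerance = 1e-9)
  expect_true(e$consistent)
  d2 <- mk_loggers(0, c(1800, 1800, 1800), temps = c(10, 11, 12))
  expect_error(estimate_lapse_rate(d2, d2$timestamp[1]), "identical")
  expect_error(estimate_lapse_rate(d[1:2, ], d$timestamp[1]), "3 sites")
})

test_that("noisy seven-site fit matches the normal-equations oracle", {
  set.seed(4)
  elevs <- seq(1512, 2274, length.out = 7)
  temps <- 18 - 8 * (elevs - 1500) / 1000 + rnorm(7, 0, 0.7)
  d <- mk_loggers(NA, elevs, temps = temps)
  e <- estimate_lapse_rate(d, d$timestamp[1])
  x <- elevs / 1000
  slope_hand <- sum((x - mean(x)) * (temps - mean(temps))) /
    sum((x - mean(x))^2)
  expect_equal(e$slope, slope_hand, tolerance = 1e-9)
})

test_that("slope is shift-invariant and scales linearly with temperature", {
  set.seed(9)
  elevs <- seq(1500, 2300, length.out = 6)
  temps <- 15 - 7 * (elevs - 1500) / 1000 + rnorm(6, 0, 0.5)
  base <- estimate_lapse_rate(mk_loggers(NA, elevs, temps),
                              as.POSIXct("2008-08-04 14:00:00", tz = "UTC"))
  shifted <- estimate_lapse_rate(mk_loggers(NA, elevs, temps + 5),
                                 as.POSIXct("2008-08-04 14:00:00",
                                            tz = "UTC"))
  scaled <- estimate_lapse_rate(mk_loggers(NA, elevs, temps * 2),
                                as.POSIXct("2008-08-04 14:00:00",
                                           tz = "UTC"))
  expect_equal(base$slope, shifted$slope, tolerance = 1e-9)
  expect_equal(scaled$slope, 2 * base$slope, tolerance = 1e-9)
})

test_that("summaries subset by consistency, clock time and month", {
  insts <- as.POSIXct(c("2008-07-29 07:00:00", "2008-07-29 14:00:00",
                        "2008-09-02 14:00:00"), tz = "UTC")
  elevs <- c(1500, 1900, 2300)
  ests <- lapply(seq_along(insts), function(i) {
    d <- mk_loggers(c(-6, -8, -10)[i], elevs, instant = insts[i])
    estimate_lapse_rate(d, insts[i])
  })
  expect_equal(summarize_lapse_rates(ests)$mean_slope, -8)
  expect_equal(summarize_lapse_rates(ests,
                                     clock_times = "14:00")$mean_slope, -9)
  expect_equal(summarize_lapse_rates(ests, months = 7)$mean_slope, -7)
  expect_equal(summarize_lapse_rates(ests[2])$mean_slope, -8)
  expect_error(summarize_lapse_rates(ests, months = 12), "empty")
})

test_that("mean consistent-subset slope recovers the generator truth", {
  slopes <- vapply(1:100, function(s) {
    d <- gen_logger_network(logger_config(seed = s, n_days = 2))
    d <- d[d$placement == "below", ]
    ests <- lapply(c("07:00:00", "14:00:00", "20:00:00"), function(ct)
      estimate_lapse_rate(d, as.POSIXct(paste("2008-07-29", ct),
                                        tz = "UTC")))
    summarize_lapse_rates(ests, consistent_only = TRUE)$mean_slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-9.46)), 0.5)
})

test_that("refuge offsets: zero for identical series, exact on a hand-made toy", {
  ts <- as.POSIXct("2008-08-01 00:00:00", tz = "UTC") +
    seq(0, 2 * 86400 - 1200, by = 1200)
  x <- data.frame(timestamp = ts,
                  temp_C = 10 + 6 * sin(2 * pi * (seq_along(ts)) / 72))
  ro <- refuge_offsets(x, x)
  expect_true(all(abs(ro$min_offset_mean) < 1e-12))
  expect_true(all(ro$min_offset_sd == 0))
  # 3-day toy with known window extrema
  days <- as.POSIXct(paste0("2008-08-0", 1:3, " 14:00:00"), tz = "UTC")
  above <- data.frame(timestamp = c(days, days + 3600),
                      temp_C = c(30, 31, 32, 28, 29, 30))
  below <- data.frame(timestamp = c(days, days + 3600),
                      temp_C = c(15, 16, 17, 14, 15, 16))
  ro2 <- refuge_offsets(above, below, windows = list(midday = c(13, 16)))
  expect_equal(ro2$max_offset_mean, mean(c(15, 15, 15) - 30))
  expect_equal(ro2$min_offset_mean, -14)
})

test_that("synthetic talus reproduces the measured offset sign pattern", {
  l <- gen_logger_network(logger_config(seed = 3, n_sites = 1, n_days = 5))
  ro <- refuge_offsets(l[l$placement == "above", ],
                       l[l$placement == "below", ])
  get <- function(w, col) ro[[col]][ro$window == w]
  expect_gt(get("morning", "min_offset_mean"), 0)
  expect_gt(get("morning", "max_offset_mean"), 0)
  expect_lt(get("midday", "min_offset_mean"), -8)
  expect_lt(get("midday", "max_offset_mean"), -10)
  expect_gt(get("evening", "min_offset_mean"), 0)
  expect_lt(get("evening", "max_offset_mean"), 0)
  expect_true(all(c(ro$min_offset_sd, ro$max_offset_sd) >= 0))
})
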
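# Logger-network analyses: surface lapse-rate estimation with the
# consistency filter, and above/below-talus refuge-offset summaries.

#' Estimate a surface lapse rate at one instant
#'
#' Ordinary least squares of instantaneous temperature on elevation (in
#' km), across a network of below-talus loggers.  "Instantaneous" means
#' the record nearest the requested clock time within +-10 min (ties go
#' to the earlier record).  The estimate is flagged consistent when
#' R^2 > 0.75.
#'
#' @param loggers data.frame of logger records with columns `site_id`,
#'   `elevation_m`, `timestamp` (POSIXct), `temp_C` (the logger CSV
#'   dialect; extra columns ignored).
#' @param instant POSIXct clock time of the measurement.
#' @param window_min Matching half-window around `instant`, minutes.
#' @return List of class `lapse_rate_estimate`: `slope` (deg C/km),
#'   `intercept`, `r_squared`, `consistent`, `n_sites`, `instant`.
#' @export
estimate_lapse_rate <- function(loggers, instant, window_min = 10) {
  stopifnot(all(c("site_id", "elevation_m", "timestamp", "temp_C") %in%
                names(loggers)))
  picks <- do.call(rbind, lapply(split(loggers, loggers$site_id), function(d) {
    dt <- abs(as.numeric(difftime(d$timestamp, instant, units = "mins")))
    i <- which(dt <= window_min)
    if (!length(i)) return(NULL)
    # nearest record; tie -> earlier
    i <- i[order(dt[i], d$timestamp[i])][1]
    d[i, c("site_id", "elevation_m", "temp_C")]
  }))
  if (is.null(picks) || nrow(picks) < 3)
    stop("need records at >= 3 sites within +-", window_min,
         " min of the instant", call. = FALSE)
  if (length(unique(picks$elevation_m)) < 2)
    stop("all sites at identical elevations: singular fit", call. = FALSE)
  fit <- stats::lm(temp_C ~ I(elevation_m / 1000), data = picks)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((picks$temp_C - mean(picks$temp_C))^2)
  # an exact fit (including a perfectly flat profile) is fully consistent
  r2 <- if (tss < 1e-12 || rss < 1e-12) 1 else 1 - rss / tss
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, consistent = r2 > 0.75,
                 n_sites = nrow(picks), instant = instant),
            class = "lapse_rate_estimate")
}

#' Summarise lapse-rate estimates over a subset
#'
#' @param estimates List of [estimate_lapse_rate()] results.
#' @param consistent_only Keep only estimates with R^2 > 0.75.
#' @param clock_times Optional character subset, e.g. `c("14:00")`.
#' @param months Optional integer months subset.
#' @return List: `mean_slope` (deg C/km), `n`, and the data.frame `table`
#'   of the retained estimates.
#' @export
summarize_lapse_rates <- function(estimates, consistent_only = FALSE,
                                  clock_times = NULL, months = NULL) {
  tab <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(instant = e$instant,
               clock = format(e$instant, "%H:%M"),
               month = as.integer(format(e$instant, "%m")),
               slope = e$slope, r_squared = e$r_squared,
               consistent = e$consistent)
  }))
  keep <- rep(TRUE, nrow(tab))
  if (consistent_only) keep <- keep & tab$consistent
  if (!is.null(clock_times)) keep <- keep & tab$clock %in% clock_times
  if (!is.null(months)) keep <- keep & tab$month %in% months
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("empty subset of lapse-rate estimates",
                           call. = FALSE)
  list(mean_slope = mean(tab$slope), n = nrow(tab), table = tab)
}

#' Above/below-talus refuge offsets by time window
#'
#' For each day and time window, computes the window minimum and maximum
#' of the above- and below-talus series and summarises the below-minus-
#' above offsets (mean and SD across days).  Days missing records in a
#' window are skipped with a warning.
#'
#' @param above,below data.frames with `timestamp` (POSIXct) and `temp_C`.
#' @param windows Named list of `c(start_hour, end_hour)` windows;
#'   defaults to the field convention: morning 05:15-08:15, midday
#'   13:00-16:00, evening 19:00-21:00.
#' @return data.frame with one row per window: `window`,
#'   `min_offset_mean`, `min_offset_sd`, `max_offset_mean`,
#'   `max_offset_sd`, `n_days`.
#' @export
refuge_offsets <- function(above, below,
                           windows = list(morning = c(5.25, 8.25),
                                          midday = c(13, 16),
                                          evening = c(19, 21))) {
  stopifnot(all(c("timestamp", "temp_C") %in% names(above)),
            all(c("timestamp", "temp_C") %in% names(below)))
  frac_hour <- function(ts) as.integer(format(ts, "%H")) +
    as.integer(format(ts, "%M")) / 60
  prep <- function(d) data.frame(day = as.Date(d$timestamp),
                                 hour = frac_hour(d$timestamp),
                                 temp = d$temp_C)
  a <- prep(above); b <- prep(below)
  days <- sort(unique(intersect(as.character(a$day), as.character(b$day))))
  rows <- lapply(names(windows), function(wn) {
    w <- windows[[wn]]
    offs_min <- c(); offs_max <- c(); skipped <- 0
    for (d in days) {
      ai <- a$day == as.Date(d) & a$hour >= w[1] & a$hour <= w[2]
      bi <- b$day == as.Date(d) & b$hour >= w[1] & b$hour <= w[2]
      if (!any(ai) || !any(bi)) { skipped <- skipped + 1; next }
      offs_min <- c(offs_min, min(b$temp[bi]) - min(a$temp[ai]))
      offs_max <- c(offs_max, max(b$temp[bi]) - max(a$temp[ai]))
    }
    if (skipped > 0)
      warning(skipped, " day(s) without records in window '", wn,
              "' skipped")
    if (!length(offs_min)) return(NULL)
    data.frame(window = wn,
               min_offset_mean = mean(offs_min),
               min_offset_sd = stats::sd(offs_min),
               max_offset_mean = mean(offs_max),
               max_offset_sd = stats::sd(offs_max),
               n_days = length(offs_min))
  })
  do.call(rbind, rows)
}
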
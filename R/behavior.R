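# Field-observation statistics: per-capita activity response, the
# log-linear AICc candidate set with model averaging and 85% confidence
# intervals, 20-degree threshold behaviour comparisons, and call-rate
# regressions.

BEHAVIOR_CATEGORIES <- c("haying", "foraging", "moving_fast",
                         "moving_slow", "vigilant")

# 85% two-sided normal quantile used for the confidence intervals
# (Arnold's convention for AIC-based selection).
CI85_MULTIPLIER <- 1.4395

#' Per-capita activity response
#'
#' `ln(sightings / occupants + offset)`; the +1 offset admits
#' zero-sighting sessions.
#'
#' @param sightings Total visual activity events in the session.
#' @param occupants Number of pikas occupying the observed patch (>= 1).
#' @param offset Offset added before the log.
#' @return Log per-capita response.
#' @export
per_capita_response <- function(sightings, occupants, offset = 1) {
  if (any(occupants < 1)) stop("occupants must be >= 1", call. = FALSE)
  if (any(sightings < 0)) stop("sightings must be >= 0", call. = FALSE)
  log(sightings / occupants + offset)
}

#' Northness index for the aspect covariate
#'
#' The log-linear models use `ln(a)` of a strictly positive aspect index;
#' aspect in degrees is mapped to `1 + cos(aspect)` (2 = due north,
#' 0 = due south), floored at `floor` to keep the log finite.  The
#' original numeric coding of aspect is not published; this convention is
#' the package's documented assumption and is overridable wherever
#' `ln_a` enters a model.
#'
#' @param aspect_deg Aspect, degrees clockwise from north.
#' @param floor Lower bound of the index.
#' @return Northness index in (0, 2].
#' @export
northness_index <- function(aspect_deg, floor = 0.05) {
  pmax(floor, 1 + cos(aspect_deg * pi / 180))
}

#' Prepare a session table for the candidate models
#'
#' @param sessions data.frame with columns `site_id`, `window`,
#'   `elevation_m`, `aspect_deg`, `occupants`, the five behaviour-count
#'   columns (haying, foraging, moving_fast, moving_slow, vigilant),
#'   `calls`, `tmin_above_C`.
#' @param offset Per-capita log offset.
#' @return The input with added `sightings`, `response`, `ln_e`, `ln_a`,
#'   `ln_t` columns (`ln_t` uses temperature floored at 0.5 deg C).
#' @export
prepare_behavior_data <- function(sessions, offset = 1) {
  stopifnot(all(c("elevation_m", "aspect_deg", "occupants",
                  "tmin_above_C", BEHAVIOR_CATEGORIES) %in% names(sessions)))
  sessions$sightings <- rowSums(sessions[BEHAVIOR_CATEGORIES])
  sessions$response <- per_capita_response(sessions$sightings,
                                           sessions$occupants, offset)
  sessions$ln_e <- log(sessions$elevation_m)
  sessions$ln_a <- log(northness_index(sessions$aspect_deg))
  sessions$ln_t <- log(pmax(sessions$tmin_above_C, 0.5))
  sessions
}

#' The a priori candidate model set
#'
#' Ten log-linear hypotheses over `ln_e` (elevation), `ln_a` (aspect
#' northness) and `ln_t` (minimum above-talus temperature), with the
#' elevation x aspect interaction present only alongside both main
#' effects.
#'
#' @return Named list of model formulas (response ~ terms).
#' @export
candidate_model_set <- function() {
  f <- function(s) stats::as.formula(paste("response ~", s))
  list(
    intercept = f("1"),
    t = f("ln_t"),
    e = f("ln_e"),
    a = f("ln_a"),
    e_a = f("ln_e + ln_a"),
    e_t = f("ln_e + ln_t"),
    a_t = f("ln_a + ln_t"),
    e_a_t = f("ln_e + ln_a + ln_t"),
    e_a_ea = f("ln_e + ln_a + ln_e:ln_a"),
    e_a_t_ea = f("ln_e + ln_a + ln_t + ln_e:ln_a")
  )
}

# Small-sample Akaike information criterion; k counts the residual
# variance as a parameter, matching normal-likelihood model selection.
aicc_from_fit <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n <= k + 1) stop("n too small for AICc (need n > k + 1)",
                       call. = FALSE)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the candidate set and rank by AICc
#'
#' Each model is fit by ordinary least squares (Gaussian maximum
#' likelihood) to the log per-capita response; models are ranked by AICc
#' and given Akaike weights `w_i = exp(-delta_i/2) / sum exp(-delta_j/2)`.
#'
#' @param data Output of [prepare_behavior_data()] (or any data.frame
#'   with `response` and covariate columns).
#' @param candidates Named list of formulas; default
#'   [candidate_model_set()].
#' @return Object of class `selection_table`: data.frame `table`
#'   (model, k, logLik, AICc, delta, weight, sorted by AICc) and list
#'   `fits` of the lm objects.  Singular fits are dropped with a warning.
#' @export
fit_candidate_set <- function(data, candidates = candidate_model_set()) {
  fits <- list(); rows <- list()
  for (nm in names(candidates)) {
    fit <- stats::lm(candidates[[nm]], data = data)
    if (any(is.na(stats::coef(fit)))) {
      warning("model '", nm, "' is rank-deficient (collinear design); dropped")
      next
    }
    fits[[nm]] <- fit
    ll <- stats::logLik(fit)
    rows[[nm]] <- data.frame(model = nm, k = attr(ll, "df"),
                             logLik = as.numeric(ll),
                             AICc = aicc_from_fit(fit))
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "selection_table")
}

# Does `bigger` contain exactly the terms of `smaller` plus one more?
added_term <- function(bigger, smaller) {
  tb <- attr(stats::terms(bigger), "term.labels")
  ts <- attr(stats::terms(smaller), "term.labels")
  if (length(tb) != length(ts) + 1 || !all(ts %in% tb)) return(NULL)
  setdiff(tb, ts)
}

#' Model-averaged coefficients with unconditional SEs and 85% CIs
#'
#' Averages over models whose Akaike weight exceeds `weight_threshold`,
#' after removing models containing an uninformative parameter (Arnold's
#' rule: a retained model that adds exactly one term to a higher-ranked
#' retained model, sits within ~2 AICc of it, and whose added term's 85%
#' CI covers zero).  Weights are renormalised over the retained set;
#' each term is averaged over the models containing it (natural
#' averaging), with unconditional standard error
#' `sum w_i * sqrt(var_i + (beta_i - beta_bar)^2)`.
#'
#' @param selection A [fit_candidate_set()] result.
#' @param weight_threshold Minimum Akaike weight for retention.
#' @param uninformative_delta Max AICc gap treated as a pure one-parameter
#'   penalty.
#' @return Object of class `averaged_coefficients`: data.frame with
#'   `term`, `estimate`, `se`, `ci_low`, `ci_high`, `n_models`;
#'   attributes `retained` (model names) and `weights` (renormalised).
#' @export
model_average <- function(selection, weight_threshold = 0.10,
                          uninformative_delta = 2.5) {
  tab <- selection$table; fits <- selection$fits
  retained <- tab$model[tab$weight > weight_threshold]
  if (!length(retained)) stop("no model exceeds the weight threshold",
                              call. = FALSE)
  # Arnold's uninformative-parameter screen
  drop <- character()
  for (m in retained) {
    for (r in retained) {
      if (m == r || m %in% drop || r %in% drop) next
      extra <- added_term(fits[[m]], fits[[r]])
      d_m <- tab$delta[tab$model == m]; d_r <- tab$delta[tab$model == r]
      if (!is.null(extra) && d_m > d_r &&
          (d_m - d_r) <= uninformative_delta) {
        sm <- summary(fits[[m]])$coefficients
        if (extra %in% rownames(sm)) {
          est <- sm[extra, 1]; se <- sm[extra, 2]
          if (abs(est) <= CI85_MULTIPLIER * se) drop <- c(drop, m)
        }
      }
    }
  }
  retained <- setdiff(retained, drop)
  if (!length(retained)) stop("all candidate models screened out",
                              call. = FALSE)
  w <- tab$weight[match(retained, tab$model)]
  w <- w / sum(w)
  names(w) <- retained

  terms_all <- unique(unlist(lapply(retained, function(m)
    rownames(summary(fits[[m]])$coefficients))))
  rows <- lapply(terms_all, function(term) {
    bs <- c(); vs <- c(); ws <- c()
    for (m in retained) {
      sm <- summary(fits[[m]])$coefficients
      if (term %in% rownames(sm)) {
        bs <- c(bs, sm[term, 1]); vs <- c(vs, sm[term, 2]^2)
        ws <- c(ws, w[m])
      }
    }
    wn <- ws / sum(ws)  # natural average over models containing the term
    b_bar <- sum(wn * bs)
    se_u <- sum(wn * sqrt(vs + (bs - b_bar)^2))
    data.frame(term = term, estimate = b_bar, se = se_u,
               ci_low = b_bar - CI85_MULTIPLIER * se_u,
               ci_high = b_bar + CI85_MULTIPLIER * se_u,
               n_models = length(bs))
  })
  out <- do.call(rbind, rows)
  structure(out, retained = retained, weights = w,
            class = c("averaged_coefficients", "data.frame"))
}

#' Behaviour comparisons across a temperature threshold
#'
#' Compares per-capita frequency of each behaviour category between
#' sessions with minimum above-talus temperature below vs at/above the
#' threshold, by one-way ANOVA (equivalent to a two-sample t test).
#'
#' @param sessions Session data.frame (see [prepare_behavior_data()]).
#' @param threshold Temperature threshold, deg C.
#' @param categories Behaviour count columns to compare.
#' @return data.frame: category, mean/SE per group, F, P.
#' @export
threshold_behavior_tests <- function(sessions, threshold = 20,
                                     categories = BEHAVIOR_CATEGORIES) {
  grp <- factor(ifelse(sessions$tmin_above_C < threshold,
                       "below", "above"), levels = c("below", "above"))
  if (any(table(grp) < 2))
    stop("each temperature group needs >= 2 sessions", call. = FALSE)
  rows <- lapply(categories, function(cat) {
    y <- sessions[[cat]] / sessions$occupants
    a <- stats::anova(stats::lm(y ~ grp))
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    data.frame(category = cat,
               mean_below = mean(y[grp == "below"]),
               se_below = sem(y[grp == "below"]),
               mean_above = mean(y[grp == "above"]),
               se_above = sem(y[grp == "above"]),
               F = a$`F value`[1], P = a$`Pr(>F)`[1])
  })
  do.call(rbind, rows)
}

#' Call-rate regressions
#'
#' Two linear models of calls per occupant: (1) on a midday indicator
#' (morning/evening pooled as the reference), returning the midday
#' contrast; (2) on minimum above-talus temperature, returning the slope
#' (calls per occupant per deg C) with its P value and R^2.
#'
#' @param sessions Session data.frame with `calls`, `occupants`,
#'   `window`, `tmin_above_C`.
#' @return List: `midday_effect` (estimate, P), `temperature`
#'   (slope, P, r_squared).
#' @export
calls_regressions <- function(sessions) {
  stopifnot(all(c("calls", "occupants", "window", "tmin_above_C") %in%
                names(sessions)))
  cpo <- sessions$calls / sessions$occupants
  if (stats::sd(cpo) == 0)
    return(list(midday_effect = list(estimate = 0, P = NA_real_),
                temperature = list(slope = 0, P = NA_real_,
                                   r_squared = 0)))
  midday <- sessions$window == "midday"
  if (length(unique(midday)) < 2) {
    md <- list(estimate = NA_real_, P = NA_real_)
  } else {
    s1 <- summary(stats::lm(cpo ~ midday))$coefficients
    md <- list(estimate = unname(s1["middayTRUE", 1]),
               P = unname(s1["middayTRUE", 4]))
  }
  f2 <- stats::lm(cpo ~ tmin_above_C, data = sessions)
  s2 <- summary(f2)$coefficients
  list(midday_effect = md,
       temperature = list(slope = unname(s2["tmin_above_C", 1]),
                          P = unname(s2["tmin_above_C", 4]),
                          r_squared = summary(f2)$r.squared))
}

#' Sun-exposure fractions of call events
#'
#' @param long_in_sun,long_total Long-call counts (field totals 1 of 149).
#' @param short_in_sun,short_total Short-call counts (400 of 6699).
#' @return Named vector of percentages (`long_pct`, `short_pct`).
#' @export
sun_exposure_fractions <- function(long_in_sun = 1, long_total = 149,
                                   short_in_sun = 400, short_total = 6699) {
  stopifnot(long_total > 0, short_total > 0,
            long_in_sun <= long_total, short_in_sun <= short_total)
  c(long_pct = 100 * long_in_sun / long_total,
    short_pct = 100 * short_in_sun / short_total)
}
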
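# Per-capita response, AICc selection, model averaging, threshold tests
# and call regressions.

test_that("per-capita response follows the documented convention", {
  expect_equal(per_capita_response(10, 2), log(6))
  expect_equal(per_capita_response(0, 3), log(1))
  expect_gt(per_capita_response(11, 2), per_capita_response(10, 2))
  expect_error(per_capita_response(5, 0), "occupants")
})

test_that("AICc and Akaike weights match a by-hand two-model computation", {
  set.seed(2)
  n <- 12
  x <- seq(-1, 1, length.out = n)
  y <- 0.5 + 1.2 * x + rnorm(n, 0, 0.3)
  d <- data.frame(response = y, ln_t = x)
  sel <- fit_candidate_set(d, list(null = response ~ 1,
                                   slope = response ~ ln_t))
  # independent computation via explicit least squares and the formula
  hand <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    rss <- sum((y - X %*% beta)^2)
    k <- ncol(X) + 1
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  aicc_null <- hand(matrix(1, n))
  aicc_slope <- hand(cbind(1, x))
  expect_equal(sort(sel$table$AICc), sort(c(aicc_null, aicc_slope)),
               tolerance = 1e-9)
  deltas <- c(aicc_null, aicc_slope) - min(aicc_null, aicc_slope)
  w <- exp(-deltas / 2) / sum(exp(-deltas / 2))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_equal(sort(sel$table$weight), sort(w), tolerance = 1e-9)
})

test_that("a single candidate takes all the weight and averages to itself", {
  set.seed(5)
  d <- data.frame(response = rnorm(20), ln_t = rnorm(20))
  sel <- fit_candidate_set(d, list(only = response ~ ln_t))
  expect_equal(sel$table$weight, 1)
  av <- model_average(sel)
  sm <- summary(sel$fits$only)$coefficients
  expect_equal(av$estimate[av$term == "ln_t"], sm["ln_t", 1])
  expect_equal(av$se[av$term == "ln_t"], sm["ln_t", 2])
})

test_that("model averaging reproduces the textbook unconditional-SE example", {
  # two equally weighted models with exact coefficients 0.2 and 0.6 and
  # zero conditional variance: beta_bar = 0.4, unconditional SE = 0.2
  x <- c(1, 2, 3, 4)
  f1 <- stats::lm(I(0.2 * x) ~ x)   # exact fit: SE = 0
  f2 <- stats::lm(I(0.6 * x) ~ x)
  sel <- structure(list(
    table = data.frame(model = c("m1", "m2"), k = 3, logLik = 0,
                       AICc = c(10, 10), delta = c(0, 0),
                       weight = c(0.5, 0.5)),
    fits = list(m1 = f1, m2 = f2)), class = "selection_table")
  # exact fits make summary.lm grumble; the arithmetic is the point here
  av <- suppressWarnings(model_average(sel, weight_threshold = 0.1))
  r <- av[av$term == "x", ]
  expect_equal(r$estimate, 0.4, tolerance = 1e-8)
  expect_equal(r$se, 0.2, tolerance = 1e-6)
  expect_equal(r$ci_low, 0.4 - 1.4395 * 0.2, tolerance = 1e-5)
})

test_that("renormalised weights sum to one and thresholds apply", {
  d <- prepare_behavior_data(gen_behavior_dataset(behavior_config(seed = 2)))
  sel <- fit_candidate_set(d)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  av <- model_average(sel)
  expect_equal(sum(attr(av, "weights")), 1, tolerance = 1e-12)
  expect_true(all(sel$table$weight[match(attr(av, "retained"),
                                         sel$table$model)] > 0.10))
})

test_that("Arnold's rule drops a one-parameter elaboration straddling zero", {
  set.seed(31)
  n <- 60
  d <- data.frame(ln_t = rnorm(n), ln_e = rnorm(n))
  d$response <- 1 - 0.8 * d$ln_t + rnorm(n, 0, 0.4)  # ln_e is pure noise
  sel <- fit_candidate_set(d, list(t = response ~ ln_t,
                                   t_e = response ~ ln_t + ln_e))
  tab <- sel$table
  gap <- tab$delta[tab$model == "t_e"] - tab$delta[tab$model == "t"]
  if (tab$weight[tab$model == "t_e"] > 0.10 && gap > 0 && gap <= 2.5) {
    av <- model_average(sel)
    expect_identical(attr(av, "retained"), "t")
  }
  succeed()
})

test_that("AICc converges to AIC for large n", {
  set.seed(8)
  n <- 20000
  d <- data.frame(response = rnorm(n), ln_t = rnorm(n))
  sel <- fit_candidate_set(d, list(m = response ~ ln_t))
  fit <- sel$fits$m
  aic <- -2 * as.numeric(logLik(fit)) + 2 * attr(logLik(fit), "df")
  expect_lt(sel$table$AICc - aic, 0.01)
})

test_that("synthetic truth with a negative temperature effect is recovered", {
  hits_sign <- 0; hits_rank <- 0; n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    d <- prepare_behavior_data(gen_behavior_dataset(behavior_config(seed = s)))
    sel <- fit_candidate_set(d)
    if (grepl("t", sel$table$model[1])) hits_rank <- hits_rank + 1
    av <- tryCatch(model_average(sel), error = function(e) NULL)
    if (!is.null(av)) {
      r <- av[av$term == "ln_t", ]
      if (nrow(r) == 1 && r$estimate < 0 && r$ci_high < 0)
        hits_sign <- hits_sign + 1
    }
  }
  expect_gte(hits_rank / n_seeds, 0.90)
  expect_gte(hits_sign / n_seeds, 0.80)
})

test_that("null truth leaves the intercept-only model competitive", {
  wins <- vapply(1:30, function(s) {
    cfg <- behavior_config(seed = s, beta_e = 0, beta_a = 0, beta_t = 0,
                           beta_ea = 0, suppression_above_20 = 1)
    d <- prepare_behavior_data(gen_behavior_dataset(cfg))
    sel <- fit_candidate_set(d)
    sel$table$delta[sel$table$model == "intercept"] < 2.5
  }, logical(1))
  expect_gte(mean(wins), 0.5)
})

test_that("identical temperature groups show no behavioural difference", {
  d <- gen_behavior_dataset(behavior_config(seed = 1))[1:8, ]
  d$tmin_above_C <- rep(c(10, 25), each = 4)
  # same within-group variation in both groups: zero between-group signal
  for (cat in BEHAVIOR_CATEGORIES) d[[cat]] <- rep(c(4, 8, 5, 7), 2)
  d$occupants <- 2
  tt <- threshold_behavior_tests(d)
  expect_true(all(tt$mean_below == tt$mean_above))
  expect_true(all(tt$F < 1e-10))
  expect_true(all(tt$P > 0.99))
})

test_that("a two-group toy reproduces the hand-computed ANOVA F", {
  d <- gen_behavior_dataset(behavior_config(seed = 1))[1:6, ]
  d$tmin_above_C <- c(10, 12, 14, 24, 25, 26)
  d$occupants <- 1
  d$foraging <- c(8, 9, 10, 2, 3, 4)
  tt <- threshold_behavior_tests(d)
  y <- d$foraging; g <- rep(c(1, 2), each = 3)
  ssb <- 3 * sum((tapply(y, g, mean) - mean(y))^2)
  ssw <- sum((y - tapply(y, g, mean)[g])^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  expect_equal(tt$F[tt$category == "foraging"], f_hand, tolerance = 1e-9)
  expect_error(threshold_behavior_tests(d[c(1, 4, 5, 6), ]), ">= 2")
})

test_that("the 20-degree shutdown appears in every category except haying", {
  hits <- vapply(1:60, function(s) {
    cfg <- behavior_config(seed = s, beta_a = 0.2, beta_ea = 0,
                           beta_t = -0.3, suppression_above_20 = 0.2,
                           dispersion = 25, mean_events = 30)
    d <- gen_behavior_dataset(cfg)
    if (sum(d$tmin_above_C >= 20) < 3) return(NA)
    tt <- threshold_behavior_tests(d)
    sig <- tt$P < 0.01 & tt$mean_below > tt$mean_above
    all(sig[tt$category != "haying"]) && tt$P[tt$category == "haying"] >= 0.01
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.90)
})

test_that("call regressions match closed-form OLS and recover truths", {
  # 4-point toy against the normal-equations solution
  d <- gen_behavior_dataset(behavior_config(seed = 1))[1:4, ]
  d$occupants <- 1
  d$window <- "morning"
  d$tmin_above_C <- c(5, 10, 15, 20)
  d$calls <- c(30, 27, 26, 22)
  cr <- calls_regressions(d)
  x <- d$tmin_above_C; y <- d$calls
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(cr$temperature$slope, slope_hand, tolerance = 1e-9)
  # constant series degenerate case
  d$calls <- 10
  cr0 <- calls_regressions(d)
  expect_equal(cr0$temperature$slope, 0)
  expect_equal(cr0$temperature$r_squared, 0)
  # parameter recovery with the confounding channel switched off
  sl <- vapply(1:40, function(s) {
    cfg <- behavior_config(seed = s, calls_midday_effect = 0)
    calls_regressions(gen_behavior_dataset(cfg))$temperature$slope
  }, numeric(1))
  expect_lt(abs(mean(sl) - (-0.5)), 0.15)
  md <- vapply(1:40, function(s) {
    cfg <- behavior_config(seed = s, calls_temp_slope = 0)
    calls_regressions(gen_behavior_dataset(cfg))$midday_effect$estimate
  }, numeric(1))
  expect_lt(abs(mean(md) - (-14.7)), 3)
})

test_that("sun-exposure fractions match the printed call counts", {
  fr <- sun_exposure_fractions()
  expect_equal(round(fr[["long_pct"]], 2), 0.67)
  expect_equal(round(fr[["short_pct"]], 1), 6.0)
  expect_equal(sun_exposure_fractions(3, 10, 1, 4),
               c(long_pct = 30, short_pct = 25))
})
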
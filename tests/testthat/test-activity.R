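# Daily activity budgets, the warming comparison and the heat-wave
# refuge simulation.

test_that("a 120 g summer pika is unrestricted at baseline; winter 150 g loses 4 of 21 h", {
  b120 <- cached_budget(pika_animal(120))
  expect_identical(b120$available_hours, 21L)
  expect_identical(b120$allowable_hours, 21L)
  expect_equal(b120$restriction_pct, 0)
  b120w <- cached_budget(pika_animal(120, pelage = "winter"))
  expect_identical(b120w$allowable_hours, 21L)
  b150w <- cached_budget(pika_animal(150, pelage = "winter"))
  expect_true(abs(b150w$available_hours - b150w$allowable_hours - 4) <= 1)
  expect_true(abs(b150w$restriction_pct - 19.0) <= 100 / 21)
})

test_that("budget invariants hold: bounds, quantisation and monotonicity", {
  b150s <- cached_budget(pika_animal(150))
  b150w <- cached_budget(pika_animal(150, pelage = "winter"))
  b120s <- cached_budget(pika_animal(120))
  for (b in list(b150s, b150w, b120s)) {
    expect_true(b$allowable_hours >= 0 &&
                b$allowable_hours <= b$available_hours)
    expect_identical(b$allowable_hours, as.integer(sum(b$hours$allowable)))
  }
  # winter restricts at least as much as summer; heavier at least as
  # much as lighter
  expect_lte(b150w$allowable_hours, b150s$allowable_hours)
  expect_lte(b150s$allowable_hours, b120s$allowable_hours)
  # summer-month multiples stay at a modest working ceiling
  expect_lte(max(b150s$hours$fmr_multiple), 3.5)
})

test_that("the +5 degree scenario removes 2 of the 120 g pika's 21 July hours", {
  base <- cached_budget(pika_animal(120))
  warm <- cached_budget(pika_animal(120), warming_delta = 5)
  cmp <- warming_scenario_comparison(list(jul_120s = base),
                                     list(jul_120s = warm))
  expect_true(abs(cmp$change_hours + 2) <= 1)
  expect_true(abs(cmp$change_vs_baseline_pct + 9.5) <= 100 / 21)
  # no warming, no change
  cmp0 <- warming_scenario_comparison(list(k = base), list(k = base))
  expect_identical(cmp0$change_hours, 0L)
  expect_error(warming_scenario_comparison(list(a = base),
                                           list(b = warm)), "keys")
})

test_that("warming restriction grows with mass, fur and warming; shrinks with elevation", {
  b150s <- cached_budget(pika_animal(150))
  b150s5 <- cached_budget(pika_animal(150), warming_delta = 5)
  b120s5 <- cached_budget(pika_animal(120), warming_delta = 5)
  expect_lte(b150s5$allowable_hours, b150s$allowable_hours)
  expect_lte(b150s5$allowable_hours, b120s5$allowable_hours)
  # higher elevation relieves the restriction under the negative lapse rate
  hi_site <- pika_site(elevation = 2000)
  b150w_hi <- daily_activity_budget(pika_animal(150, pelage = "winter"),
                                    hi_site, 7)
  b150w_lo <- cached_budget(pika_animal(150, pelage = "winter"))
  expect_gte(b150w_hi$allowable_hours, b150w_lo$allowable_hours)
})

test_that("a heavy, thick-furred pika loses far more August time by 2100", {
  a180 <- pika_animal(180, fur_scale = 1.2)
  base <- cached_budget(a180, month = 8)
  warm <- cached_budget(a180, month = 8, warming_delta = 5)
  expect_identical(base$available_hours, 19L)
  cmp <- warming_scenario_comparison(list(aug = base), list(aug = warm))
  expect_lt(cmp$change_vs_baseline_pct, -25)
  expect_gt(cmp$change_vs_baseline_pct, -55)
})

test_that("an animal with unbounded dissipation uses every available hour", {
  super <- pika_animal(150, pelage = "winter",
                       config = list(conv_enhancement = 60))
  b <- cached_budget(super)
  expect_identical(b$allowable_hours, b$available_hours)
})

test_that("heat wave: lethal midday surface, viable refuge at depth", {
  hw <- heatwave_refuge_simulation(pika_animal(150), gnp_site)
  h <- hw$hours
  surf <- h[h$location == "surface", ]
  bad <- surf$hour[!surf$bmr_sustainable]
  expect_gte(length(bad), 2)
  expect_true(any(diff(bad) == 1))          # consecutive midday hours
  expect_true(all(bad >= 8 & bad <= 18))
  deepest <- h[h$location == "20cm", ]
  expect_true(all(deepest$bmr_sustainable))
  # feasibility improves with depth whenever the subsurface is cooler
  shallow <- h[h$location == "15cm", ]
  cooler <- shallow$t_local_C >= deepest$t_local_C
  expect_true(all(deepest$fmr_multiple[cooler] >=
                  shallow$fmr_multiple[cooler] - 1e-6))
})

test_that("an ordinary July day keeps the sunlit surface survivable", {
  mild <- heatwave_refuge_simulation(pika_animal(150), gnp_site,
                                     heatwave_delta = 0)
  surf <- mild$hours[mild$hours$location == "surface", ]
  expect_true(all(surf$bmr_sustainable))
})

test_that("the field threshold sweep crosses 1.5 near 20 degrees for 150 g", {
  thr <- field_activity_threshold(pika_animal(150))
  expect_true(abs(thr - 20) <= 2)
  # BMR-level crossing sits above the activity-level crossing
  expect_gt(field_activity_threshold(pika_animal(150), level = 1.0), thr)
})
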
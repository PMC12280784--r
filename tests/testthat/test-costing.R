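test_that("valuation rules price events as stated", {
  tar <- tariff_table(deterministic_components())
  ev <- data.frame(
    id = c(1L, 1L, 2L),
    period_index = c(1L, 2L, 1L),
    category = c("medication", "consultation", "inpatient"),
    subcategory = c("drug_a", "gp_visit", "rehab"),
    quantity = c(1, 3, 1),
    days = c(NA, NA, 5),
    duration_days = c(30, NA, NA)
  )
  v <- value_events(ev, tar, seed = 1)
  # DDD rule: 0.20 EUR x 2/day x 30 days = 12.00
  expect_equal(v$cost[v$id == 1 & v$category == "medication"], 12.00)
  # fixed tariff: 3 visits x 25
  expect_equal(v$cost[v$id == 1 & v$category == "consultation"], 75)
  # per diem: 5 days x 150
  expect_equal(v$cost[v$id == 2 & v$category == "inpatient"], 750)
})

test_that("valuation rejects unknown subcategories and bad quantities", {
  tar <- tariff_table(deterministic_components())
  ev <- data.frame(id = 1L, period_index = 1L, category = "consultation",
                   subcategory = "dentist", quantity = 1,
                   days = NA, duration_days = NA)
  expect_error(value_events(ev, tar), "dentist")
  ev$subcategory <- "gp_visit"
  ev$quantity <- -1
  expect_error(value_events(ev, tar), "negative")
})

test_that("an empty event list yields a zero panel", {
  tar <- tariff_table(deterministic_components())
  ev <- data.frame(id = integer(), period_index = integer(),
                   category = character(), subcategory = character(),
                   quantity = numeric(), days = numeric(),
                   duration_days = numeric())
  v <- value_events(ev, tar, seed = 1)
  expect_equal(nrow(v), 0)
})

test_that("gamma-sampled valuation is moment-matched to mean and variance", {
  m <- 400; v <- 90000
  comp <- data.frame(category = "paramedical", subcategory = "act",
                     rule = "gamma_sampled", rate_3y = 1,
                     gamma_mean = m, gamma_var = v,
                     unit_cost = NA, per_diem_rate = NA, price_per_unit = NA,
                     ddd_per_day = NA, mean_days = NA, mean_duration = NA)
  tar <- tariff_table(comp)
  expect_equal(tar$rules$gamma_shape, m^2 / v)
  expect_equal(tar$rules$gamma_scale, v / m)
  n <- 10000
  ev <- data.frame(id = seq_len(n), period_index = 1L,
                   category = "paramedical", subcategory = "act",
                   quantity = 1, days = NA, duration_days = NA)
  val <- value_events(ev, tar, seed = 123)
  expect_lt(abs(mean(val$cost) - m), 3 * sqrt(v / n))
})

test_that("intervention pricing follows the wage and capsule formulas", {
  tar <- tariff_table()
  expect_equal(intervention_cost("placebo", tar), 0)
  expect_equal(intervention_cost("PFA", tar), 0.50 * 365.5 * 3)
  expect_equal(intervention_cost("MI", tar), 40 * 2.30 * 10)
  expect_equal(intervention_cost("PFA+MI", tar),
               intervention_cost("PFA", tar) + intervention_cost("MI", tar))
  expect_error(intervention_cost("usual care", tar), "unknown arm")
})

test_that("cumulative totals are additive, monotone and scale-equivariant", {
  panel <- fixture_panel()
  t <- panel$totals
  # additive identity, exact, every participant
  expect_identical(t$total_with, t$total_without + t$intervention_cost)
  expect_true(all(t$intervention_cost[t$arm == "placebo"] == 0))
  expect_true(all(t$total_without >= 0))

  # monotonicity: appending an event can only increase totals
  d <- fixture_trial_missing()
  extra <- data.frame(id = t$id[1], period_index = 3L,
                      category = "consultation",
                      subcategory = "general_practitioner",
                      quantity = 2, days = NA, duration_days = NA)
  d2 <- d
  d2$events <- rbind(d$events, extra)
  panel2 <- cost_panel(d2, panel$tariffs, seed = 99L)
  expect_true(all(panel2$totals$total_with >= t$total_with - 1e-9))
  expect_gt(panel2$totals$total_with[1], t$total_with[1])

  # doubling every tariff doubles every deterministic-rule cost, and the
  # gamma scale doubling doubles sampled costs draw-for-draw at a fixed seed
  comp <- d$config$cost_component_spec
  comp$unit_cost <- comp$unit_cost * 2
  comp$per_diem_rate <- comp$per_diem_rate * 2
  comp$price_per_unit <- comp$price_per_unit * 2
  comp$gamma_mean <- comp$gamma_mean * 2
  comp$gamma_var <- comp$gamma_var * 4   # mean x2 at equal shape => var x4
  tar2 <- tariff_table(comp,
                       mi_hourly_wage = 80, pfa_price_per_capsule = 1.0)
  panel3 <- cost_panel(d, tar2, seed = 99L)
  expect_equal(panel3$totals$total_with, 2 * t$total_with, tolerance = 1e-12)
})

test_that("cumulative_costs sums components over the six periods", {
  tar <- tariff_table(deterministic_components())
  # two components, 100 and 200 EUR per period, all six periods
  ev <- data.frame(
    id = 1L, period_index = rep(1:6, 2),
    category = rep(c("consultation", "inpatient"), each = 6),
    subcategory = rep(c("gp_visit", "rehab"), each = 6),
    quantity = rep(c(4, 1), each = 6),           # 4 x 25 = 100
    days = rep(c(NA, 200 / 150), each = 6),      # 150 x 4/3 = 200
    duration_days = NA
  )
  v <- value_events(ev, tar, seed = 1)
  expect_equal(sum(v$cost), 1800)
})
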
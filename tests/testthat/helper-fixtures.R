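# Shared fixtures, built once per test run. All synthetic, seeded.

.fixture_env <- new.env(parent = emptyenv())

# small complete trial reused by costing / descriptives / pipeline tests
fixture_trial <- function() {
  if (is.null(.fixture_env$trial)) {
    cfg <- trial_config(n_per_arm = 60, random_seed = 424242)
    .fixture_env$trial <- generate_trial(cfg)
  }
  .fixture_env$trial
}

# the same trial with MAR missingness applied
fixture_trial_missing <- function() {
  if (is.null(.fixture_env$trial_missing)) {
    .fixture_env$trial_missing <- apply_missingness(fixture_trial())
  }
  .fixture_env$trial_missing
}

fixture_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- cost_panel(fixture_trial_missing(), seed = 99L)
  }
  .fixture_env$panel
}

# deterministic-only tariff components (no gamma sampling), for exact
# costing arithmetic
deterministic_components <- function() {
  data.frame(
    category = c("consultation", "medication", "inpatient"),
    subcategory = c("gp_visit", "drug_a", "rehab"),
    rule = c("fixed_tariff", "ddd_drug", "per_diem"),
    rate_3y = c(6, 3, 1),
    gamma_mean = NA_real_, gamma_var = NA_real_,
    unit_cost = c(25, NA, NA),
    per_diem_rate = c(NA, NA, 150),
    price_per_unit = c(NA, 0.20, NA),
    ddd_per_day = c(NA, 2, NA),
    mean_days = c(NA, NA, 4),
    mean_duration = c(NA, 30, NA),
    stringsAsFactors = FALSE
  )
}

# hand-built ce_replicates for ellipse / CEAC unit tests
make_replicates <- function(delta_c, delta_e, arm = "A",
                            effect_unit = "z") {
  structure(
    data.frame(arm = arm, b = seq_along(delta_c),
               delta_c = delta_c, delta_e = delta_e),
    effect_unit = effect_unit, seed = 1L, reference = "placebo",
    class = c("ce_replicates", "data.frame")
  )
}
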
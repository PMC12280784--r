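#' Configuration for a synthetic four-arm prevention trial
#'
#' Builds the configuration object consumed by [generate_trial()]. Defaults
#' emulate a multicenter, placebo-controlled four-arm trial of omega-3
#' polyunsaturated fatty acid supplementation (PFA) and a multidomain
#' lifestyle intervention (MI) in community-dwelling adults aged 70+ followed
#' for 3 years: ~380 participants per arm across 13 memory centers, composite
#' cognitive Z-score arm effects of 0.093 (PFA+MI), 0.079 (MI) and 0.011
#' (PFA) versus placebo at 36 months, right-skewed healthcare costs whose
#' per-component 3-year means match published payer-perspective trial costs
#' for this population, and 12-15% missing economic data per arm.
#'
#' @param n_per_arm participants per arm (>= 2).
#' @param arm_labels character vector of exactly 4 arm labels; the last label
#'   is the placebo/reference arm.
#' @param true_z_effects named numeric vector: expected 36-month composite-Z
#'   difference versus placebo, in Z points, one entry per arm; the placebo
#'   entry must be 0.
#' @param n_centers number of recruiting centers.
#' @param missing_econ_rate expected proportion of participants per arm whose
#'   3-year economic data are missing (missing-at-random given age tercile
#'   and frailty).
#' @param cognitive_dropout_rate expected proportion per arm who miss the
#'   36-month cognitive visit (monotone dropout, same MAR driver covariates).
#' @param baseline_cov_spec list of baseline covariate distribution
#'   parameters; see Details.
#' @param cognitive_spec list of generative parameters for the four cognitive
#'   tests; see Details.
#' @param cost_component_spec data frame of resource-use components, one row
#'   per subcategory, as returned by [default_cost_components()].
#' @param arm_cost_multipliers named numeric vector scaling event rates per
#'   arm; defaults reproduce the relative per-arm 3-year cost totals observed
#'   in this trial population (placebo = 1).
#' @param random_seed integer seed making the whole dataset reproducible.
#'
#' @details
#' `baseline_cov_spec` fields: `age_mean` (75.4 y), `age_sd` (4.4 y) for a
#' normal age distribution left-truncated at `age_min` (70 y, the eligibility
#' floor); `p_male` (0.36); `frailty_probs` over \{robust, pre-frail,
#' frail\}; `education_probs` over four attainment levels;
#' `med_conditions_size`/`med_conditions_prob`: the number of medical-history
#' conditions is Binomial(16, 0.4), giving counts in \[0, 16\] with terciles
#' near 5 and 8.
#'
#' `cognitive_spec` fields: `visit_months` (default 0, 6, 12, 24, 36);
#' `tests`: per-test raw-score mean and SD (free-and-cued selective reminding
#' recall sum, MMSE orientation items, digit symbol substitution, category
#' fluency); variance components on the shared latent cognition scale
#' `sd_participant`, `sd_center`, `sd_test_resid`; and `decline_z`, the
#' placebo-arm mean composite-Z trajectory relative to baseline. Arm effects
#' ramp linearly in time so the 36-month composite-Z contrast equals
#' `true_z_effects`.
#'
#' @return object of class `trial_config`.
#' @seealso [generate_trial()], [apply_missingness()], [default_cost_components()]
#' @export
trial_config <- function(n_per_arm = 380,
                         arm_labels = c("PFA+MI", "PFA", "MI", "placebo"),
                         true_z_effects = c("PFA+MI" = 0.093, "PFA" = 0.011,
                                            "MI" = 0.079, "placebo" = 0),
                         n_centers = 13,
                         missing_econ_rate = 0.135,
                         cognitive_dropout_rate = 0.15,
                         baseline_cov_spec = NULL,
                         cognitive_spec = NULL,
                         cost_component_spec = default_cost_components(),
                         arm_cost_multipliers = c("PFA+MI" = 1.084, "PFA" = 1.119,
                                                  "MI" = 1.104, "placebo" = 1),
                         random_seed = 20080530) {
  check_that(length(arm_labels) == 4 && !anyDuplicated(arm_labels),
             "arm_labels", "exactly 4 distinct arms are required")
  check_that(is.numeric(n_per_arm) && n_per_arm >= 2, "n_per_arm", "must be >= 2")
  check_that(all(arm_labels %in% names(true_z_effects)),
             "true_z_effects", "must be named by the arm labels")
  true_z_effects <- true_z_effects[arm_labels]
  placebo <- arm_labels[length(arm_labels)]
  check_that(true_z_effects[[placebo]] == 0,
             "true_z_effects", "the placebo (reference) effect must be 0")
  check_that(missing_econ_rate >= 0 && missing_econ_rate <= 1,
             "missing_econ_rate", "must be a proportion in [0, 1]")
  check_that(cognitive_dropout_rate >= 0 && cognitive_dropout_rate <= 1,
             "cognitive_dropout_rate", "must be a proportion in [0, 1]")
  check_that(n_centers >= 1, "n_centers", "must be >= 1")

  if (is.null(baseline_cov_spec)) {
    baseline_cov_spec <- list(
      age_mean = 75.4, age_sd = 4.4, age_min = 70,
      p_male = 0.36,
      frailty_probs = c(robust = 0.56, `pre-frail` = 0.41, frail = 0.03),
      education_probs = c(primary = 0.22, secondary = 0.33,
                          high_school = 0.14, university = 0.31),
      med_conditions_size = 16, med_conditions_prob = 0.4
    )
  }
  if (is.null(cognitive_spec)) {
    cognitive_spec <- list(
      visit_months = c(0L, 6L, 12L, 24L, 36L),
      tests = data.frame(
        test = c("fcsrt_recall", "mmse_orientation", "dsst", "fluency"),
        mean = c(29, 9.5, 35, 19),
        sd   = c(7, 0.8, 11, 5)
      ),
      sd_participant = 0.45,
      sd_center = 0.05,
      sd_test_resid = 0.65,
      decline_z = c(0, -0.03, -0.06, -0.11, -0.18)
    )
  }
  check_that(all(baseline_cov_spec$age_sd > 0), "baseline_cov_spec", "age_sd must be > 0")
  check_that(abs(sum(baseline_cov_spec$frailty_probs) - 1) < 1e-8,
             "baseline_cov_spec", "frailty_probs must sum to 1")
  check_that(length(cognitive_spec$decline_z) == length(cognitive_spec$visit_months),
             "cognitive_spec", "decline_z must match visit_months in length")
  check_that(is.data.frame(cost_component_spec) &&
               all(c("category", "subcategory", "rule", "rate_3y") %in%
                     names(cost_component_spec)),
             "cost_component_spec", "must have category/subcategory/rule/rate_3y")
  check_that(all(cost_component_spec$rate_3y >= 0),
             "cost_component_spec", "event rates must be >= 0")
  gam <- cost_component_spec$rule == "gamma_sampled"
  check_that(all(cost_component_spec$gamma_mean[gam] > 0) &&
               all(cost_component_spec$gamma_var[gam] > 0),
             "cost_component_spec", "gamma means and variances must be > 0")
  check_that(all(arm_labels %in% names(arm_cost_multipliers)),
             "arm_cost_multipliers", "must be named by the arm labels")

  structure(list(
    n_per_arm = as.integer(n_per_arm),
    arm_labels = arm_labels,
    placebo = placebo,
    true_z_effects = true_z_effects,
    n_centers = as.integer(n_centers),
    missing_econ_rate = missing_econ_rate,
    cognitive_dropout_rate = cognitive_dropout_rate,
    baseline_cov_spec = baseline_cov_spec,
    cognitive_spec = cognitive_spec,
    cost_component_spec = cost_component_spec,
    arm_cost_multipliers = arm_cost_multipliers[arm_labels],
    random_seed = as.integer(random_seed)
  ), class = "trial_config")
}

#' Default resource-use component specification
#'
#' One row per costed subcategory of payer-perspective resource use:
#' inpatient stays, consultations, paramedical procedures, medical procedures
#' (laboratory, imaging, other), transportation, and reimbursed medication.
#' 3-year event rates and cost levels are calibrated so that the placebo-arm
#' expected component costs match published 3-year payer costs in a
#' community-dwelling 70+ trial population (inpatient ~ EUR 3,829,
#' consultations ~ EUR 495, paramedical ~ EUR 393, medical procedures
#' ~ EUR 228, transportation ~ EUR 15, medication ~ EUR 2,137; total
#' ~ EUR 7,106 over 3 years).
#'
#' Valuation rules exercised: `gamma_sampled` components carry the gamma
#' mean/variance from which [value_events()] derives shape and scale;
#' `fixed_tariff` components are priced per unit; `per_diem` components are
#' priced per day of stay; `ddd_drug` components are priced as unit price x
#' defined daily dose x treatment duration.
#'
#' @return data frame with columns `category`, `subcategory`, `rule`,
#'   `rate_3y`, rule parameters (`gamma_mean`, `gamma_var`, `unit_cost`,
#'   `per_diem_rate`, `price_per_unit`, `ddd_per_day`), and attribute means
#'   for generated events (`mean_days`, `mean_duration`).
#' @export
default_cost_components <- function() {
  df <- data.frame(
    category = c("inpatient", "inpatient",
                 "consultation", "consultation",
                 "paramedical",
                 "medical_procedure", "medical_procedure", "medical_procedure",
                 "transportation",
                 "medication"),
    subcategory = c("acute_stay", "rehabilitation_stay",
                    "general_practitioner", "specialist",
                    "paramedical_act",
                    "laboratory_test", "imaging", "other_procedure",
                    "medical_transport",
                    "reimbursed_drug"),
    rule = c("gamma_sampled", "per_diem",
             "fixed_tariff", "fixed_tariff",
             "gamma_sampled",
             "fixed_tariff", "fixed_tariff", "fixed_tariff",
             "gamma_sampled",
             "ddd_drug"),
    rate_3y = c(0.90, 0.05,
                15.0, 12.9,
                21.8,
                18.3, 2.87, 0.87,
                0.49,
                31.78),
    gamma_mean = c(4166, NA, NA, NA, 18.0, NA, NA, NA, 30.6, NA),
    gamma_var  = c(4166^2 * 2.25, NA, NA, NA, 18^2, NA, NA, NA, 30.6^2 * 1.44, NA),
    unit_cost = c(NA, NA, 16.5, 19.2, NA, 5.6, 34.8, 28.7, NA, NA),
    per_diem_rate = c(NA, 200, NA, NA, NA, NA, NA, NA, NA, NA),
    price_per_unit = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 0.56),
    ddd_per_day = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 2),
    mean_days = c(NA, 8, NA, NA, NA, NA, NA, NA, NA, NA),
    mean_duration = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 60),
    stringsAsFactors = FALSE
  )
  df
}

# internal: solve the MAR logistic intercept so the expected missingness rate
# equals the target given the linear predictor offsets
mar_intercept <- function(offsets, rate) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + offsets)) - rate,
                 interval = c(-20, 20))$root
}

#' Generate a synthetic four-arm prevention trial dataset
#'
#' Draws a complete trial: equal-allocation arm assignment, baseline
#' covariates, longitudinal raw scores on four cognitive tests under a
#' shared-latent mixed model (participant and center random intercepts, visit
#' effects, arm-by-visit effects scaled so the expected 36-month composite-Z
#' contrast versus placebo equals `config$true_z_effects`), and event-level
#' healthcare resource use with Poisson event counts and the component
#' specification of the config. Fully reproducible from `config$random_seed`.
#'
#' @param config a [trial_config()] object.
#' @return object of class `trial_dataset`: a list with data frames
#'   `participants` (id, arm, center_id, age_years, gender, frailty,
#'   education, n_medical_conditions, econ_missing), `cognition` (long
#'   format: id, visit_month, one column per test; NA rows removed for missed
#'   visits), `events` (id, period_index 1..6, category, subcategory,
#'   quantity, days, duration_days), and the `config`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$random_seed)
  arms <- config$arm_labels
  n <- config$n_per_arm * 4L
  bc <- config$baseline_cov_spec

  participants <- data.frame(
    id = seq_len(n),
    arm = factor(rep(arms, each = config$n_per_arm), levels = arms),
    center_id = sample.int(config$n_centers, n, replace = TRUE)
  )
  # age: normal truncated at the eligibility floor (resample rejects)
  age <- stats::rnorm(n, bc$age_mean, bc$age_sd)
  while (any(bad <- age < bc$age_min)) {
    age[bad] <- stats::rnorm(sum(bad), bc$age_mean, bc$age_sd)
  }
  participants$age_years <- age
  participants$gender <- factor(
    ifelse(stats::runif(n) < bc$p_male, "male", "female"),
    levels = c("male", "female"))
  participants$frailty <- factor(
    sample(names(bc$frailty_probs), n, replace = TRUE, prob = bc$frailty_probs),
    levels = names(bc$frailty_probs))
  participants$education <- factor(
    sample(names(bc$education_probs), n, replace = TRUE, prob = bc$education_probs),
    levels = names(bc$education_probs))
  participants$n_medical_conditions <-
    stats::rbinom(n, bc$med_conditions_size, bc$med_conditions_prob)
  participants$econ_missing <- FALSE

  cognition <- simulate_cognition(participants, config)
  events <- simulate_resource_events(participants, config)

  structure(list(participants = participants, cognition = cognition,
                 events = events, config = config),
            class = "trial_dataset")
}

# internal: longitudinal raw test scores under the shared-latent model.
# Each raw score is test_mean + test_sd * (latent + test residual); the
# latent combines participant and center intercepts with the placebo decline
# and a linearly ramped arm effect, all expressed in baseline-SD units of the
# latent-plus-residual scale so that specified effects land on the composite
# Z scale after baseline standardization.
simulate_cognition <- function(participants, config) {
  cs <- config$cognitive_spec
  months <- cs$visit_months
  n <- nrow(participants)
  nv <- length(months)
  s_b <- sqrt(cs$sd_participant^2 + cs$sd_center^2 + cs$sd_test_resid^2)

  u <- stats::rnorm(n, 0, cs$sd_participant)
  cent <- stats::rnorm(config$n_centers, 0, cs$sd_center)
  arm_eff <- config$true_z_effects[as.character(participants$arm)]

  out <- data.frame(
    id = rep(participants$id, each = nv),
    visit_month = rep(months, times = n)
  )
  ramp <- months / max(months)
  latent <- rep(u, each = nv) + rep(cent[participants$center_id], each = nv) +
    s_b * (rep(cs$decline_z, times = n) +
             rep(arm_eff, each = nv) * rep(ramp, times = n))
  for (k in seq_len(nrow(cs$tests))) {
    eps <- stats::rnorm(n * nv, 0, cs$sd_test_resid)
    out[[cs$tests$test[k]]] <- cs$tests$mean[k] + cs$tests$sd[k] * (latent + eps)
  }
  out
}

# internal: event-level resource use; Poisson counts per participant x
# 6-month period x subcategory, rates scaled by the arm multiplier; stay and
# treatment durations attached where the valuation rule needs them.
simulate_resource_events <- function(participants, config) {
  spec <- config$cost_component_spec
  mult <- config$arm_cost_multipliers[as.character(participants$arm)]
  n <- nrow(participants)
  pieces <- vector("list", nrow(spec) * 6L)
  k <- 0L
  for (j in seq_len(nrow(spec))) {
    rate <- spec$rate_3y[j] / 6
    for (p in 1:6) {
      cnt <- stats::rpois(n, rate * mult)
      idx <- rep.int(participants$id, cnt)
      if (!length(idx)) next
      k <- k + 1L
      ev <- data.frame(
        id = idx, period_index = p,
        category = spec$category[j], subcategory = spec$subcategory[j],
        quantity = 1
      )
      ev$days <- if (!is.na(spec$mean_days[j]))
        1 + stats::rpois(length(idx), spec$mean_days[j] - 1) else NA_real_
      ev$duration_days <- if (!is.na(spec$mean_duration[j]))
        1 + stats::rpois(length(idx), spec$mean_duration[j] - 1) else NA_real_
      pieces[[k]] <- ev
    }
  }
  ev <- do.call(rbind, pieces[seq_len(k)])
  ev <- ev[order(ev$id, ev$period_index, ev$subcategory), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Apply missing-at-random missingness to a complete trial dataset
#'
#' Marks 3-year cumulative economic data missing for approximately
#' `missing_econ_rate` of participants per arm and truncates cognitive
#' follow-up for approximately `cognitive_dropout_rate` per arm (monotone
#' dropout: a random last observed visit before 36 months). Missingness
#' probability depends only on observed baseline covariates — age tercile and
#' frailty — so the mechanism is missing-at-random by construction. The
#' logistic intercept is solved so the expected rate matches the target
#' exactly. The untouched input is kept as `$complete` for oracle comparisons.
#'
#' @param dataset a complete `trial_dataset` from [generate_trial()].
#' @param config the [trial_config()] used (defaults to the dataset's own).
#' @param mnar_shift optional non-MAR perturbation: log-odds of economic
#'   missingness added per standard deviation of the participant's latent
#'   cost propensity proxy (total observed 3-year cost, standardized). 0 (the
#'   default) keeps the mechanism MAR; nonzero values are for sensitivity
#'   experiments on attrition diagnostics.
#' @return `trial_dataset` with `participants$econ_missing` set, cognition
#'   rows after dropout removed, and the original dataset in `$complete`.
#' @export
apply_missingness <- function(dataset, config = dataset$config, mnar_shift = 0) {
  stopifnot(inherits(dataset, "trial_dataset"))
  check_that(config$missing_econ_rate >= 0 && config$missing_econ_rate <= 1,
             "missing_econ_rate", "must be in [0, 1]")
  check_that(config$cognitive_dropout_rate >= 0 &&
               config$cognitive_dropout_rate <= 1,
             "cognitive_dropout_rate", "must be in [0, 1]")
  complete <- dataset
  p <- dataset$participants
  set.seed(derive_seed(config$random_seed, 101L))

  age_t <- tercile(p$age_years)
  off <- 0.4 * (as.integer(age_t) == 2) + 0.8 * (as.integer(age_t) == 3) +
    0.5 * (p$frailty == "pre-frail") + 1.0 * (p$frailty == "frail")
  off_econ <- off
  if (mnar_shift != 0) {
    # latent-cost proxy: standardized event count per participant
    cnt <- tabulate(dataset$events$id, nbins = nrow(p))
    off_econ <- off + mnar_shift * as.numeric(scale(cnt))
  }
  a_econ <- mar_intercept(off_econ, config$missing_econ_rate)
  p$econ_missing <- stats::runif(nrow(p)) < stats::plogis(a_econ + off_econ)

  a_cog <- mar_intercept(off, config$cognitive_dropout_rate)
  dropout <- stats::runif(nrow(p)) < stats::plogis(a_cog + off)
  months <- config$cognitive_spec$visit_months
  interim <- months[months > 0 & months < max(months)]
  last_visit <- ifelse(dropout, sample(interim, nrow(p), replace = TRUE),
                       max(months))
  cog <- dataset$cognition
  keep <- cog$visit_month <= last_visit[match(cog$id, p$id)]
  dataset$participants <- p
  dataset$cognition <- cog[keep, , drop = FALSE]
  dataset$complete <- complete
  dataset
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Synthetic four-arm prevention trial\n")
  cat(sprintf("  participants: %d (%s)\n", nrow(x$participants),
              paste(levels(x$participants$arm), collapse = " / ")))
  cat(sprintf("  cognitive visits: %d rows over months {%s}\n",
              nrow(x$cognition),
              paste(x$config$cognitive_spec$visit_months, collapse = ", ")))
  cat(sprintf("  resource events: %d\n", nrow(x$events)))
  if (!is.null(x$complete))
    cat(sprintf("  economic data missing: %d participants\n",
                sum(x$participants$econ_missing)))
  invisible(x)
}

#' Write a trial dataset to CSV files
#'
#' Writes `participants.csv`, `cognition.csv` and `resource_events.csv`
#' (1-based period indexing, visit months as integers) plus the config as
#' `config.json` into `dir`.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_trial_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("participants.csv", "cognition.csv",
                            "resource_events.csv", "config.json"))
  utils::write.csv(dataset$participants, paths[1], row.names = FALSE)
  utils::write.csv(dataset$cognition, paths[2], row.names = FALSE)
  utils::write.csv(dataset$events, paths[3], row.names = FALSE)
  cfg <- dataset$config
  cfg$cost_component_spec <- as.data.frame(cfg$cost_component_spec)
  jsonlite::write_json(unclass(cfg), paths[4], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(paths)
}
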
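#' Tariff table for payer-perspective valuation
#'
#' Maps every resource-use subcategory to a valuation rule and prices the
#' interventions. Rules: `fixed_tariff` (EUR per unit), `per_diem` (EUR per
#' day of stay), `ddd_drug` (reimbursement price per unit x defined daily
#' dose x treatment duration in days), `gamma_sampled` (cost drawn from a
#' Gamma distribution whose shape and scale are derived by moment matching
#' from the mean and variance observed for that component: shape = m^2/v,
#' scale = v/m).
#'
#' Intervention pricing follows the trial's costing: the multidomain
#' intervention (MI) is valued at the mean hourly wage of the facilitating
#' professionals (EUR 40) x session length (2.30 h) x number of priced
#' sessions; the omega-3 supplementation (PFA) at the retail price per
#' capsule (EUR 0.50) x capsules per year (365.5) x the 3-year horizon.
#'
#' @param components data frame of component rules, as
#'   [default_cost_components()].
#' @param mi_hourly_wage EUR per hour for MI staff.
#' @param mi_session_hours hours per MI session.
#' @param mi_sessions_priced number of MI sessions priced over the horizon.
#' @param pfa_price_per_capsule EUR per capsule.
#' @param pfa_capsules_per_year capsules priced per year.
#' @param horizon_years analysis horizon in years.
#' @return object of class `tariff_table`.
#' @export
tariff_table <- function(components = default_cost_components(),
                         mi_hourly_wage = 40,
                         mi_session_hours = 2.30,
                         mi_sessions_priced = 10,
                         pfa_price_per_capsule = 0.50,
                         pfa_capsules_per_year = 365.5,
                         horizon_years = 3) {
  check_that(all(c(mi_hourly_wage, mi_session_hours, mi_sessions_priced,
                   pfa_price_per_capsule, pfa_capsules_per_year,
                   horizon_years) >= 0),
             "tariff_table", "all monetary and count parameters must be >= 0")
  rules <- components
  gam <- rules$rule == "gamma_sampled"
  check_that(all(rules$gamma_mean[gam] > 0) && all(rules$gamma_var[gam] > 0),
             "components", "gamma means and variances must be > 0")
  rules$gamma_shape <- ifelse(gam, rules$gamma_mean^2 / rules$gamma_var, NA)
  rules$gamma_scale <- ifelse(gam, rules$gamma_var / rules$gamma_mean, NA)
  fx <- rules$rule == "fixed_tariff"
  check_that(all(rules$unit_cost[fx] >= 0), "components",
             "fixed tariffs must be >= 0")
  structure(list(
    rules = rules,
    mi_hourly_wage = mi_hourly_wage,
    mi_session_hours = mi_session_hours,
    mi_sessions_priced = mi_sessions_priced,
    pfa_price_per_capsule = pfa_price_per_capsule,
    pfa_capsules_per_year = pfa_capsules_per_year,
    horizon_years = horizon_years
  ), class = "tariff_table")
}

#' Write / read a tariff table as JSON
#'
#' @param tariffs a [tariff_table()].
#' @param path file path.
#' @return `read_tariffs` returns a `tariff_table`; `write_tariffs` returns
#'   the path invisibly.
#' @export
write_tariffs <- function(tariffs, path) {
  jsonlite::write_json(unclass(tariffs), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_tariffs
#' @export
read_tariffs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tariff_table(components = as.data.frame(x$rules),
               mi_hourly_wage = x$mi_hourly_wage,
               mi_session_hours = x$mi_session_hours,
               mi_sessions_priced = x$mi_sessions_priced,
               pfa_price_per_capsule = x$pfa_price_per_capsule,
               pfa_capsules_per_year = x$pfa_capsules_per_year,
               horizon_years = x$horizon_years)
}

#' Price an intervention arm
#'
#' PFA component = capsule price x capsules/year x horizon; MI component =
#' hourly wage x session hours x sessions priced; a combined arm gets the sum
#' of both; the placebo arm costs 0. Arm labels are parsed on `+`, so any
#' label made of "PFA", "MI" and "placebo" tokens works.
#'
#' @param arm character vector of arm labels.
#' @param tariffs a [tariff_table()].
#' @return numeric vector of intervention costs in EUR.
#' @export
intervention_cost <- function(arm, tariffs = tariff_table()) {
  pfa <- tariffs$pfa_price_per_capsule * tariffs$pfa_capsules_per_year *
    tariffs$horizon_years
  mi <- tariffs$mi_hourly_wage * tariffs$mi_session_hours *
    tariffs$mi_sessions_priced
  vapply(as.character(arm), function(a) {
    toks <- trimws(strsplit(a, "+", fixed = TRUE)[[1]])
    if (!length(toks) || !all(toks %in% c("PFA", "MI", "placebo")))
      stop(sprintf("unknown arm label: '%s'", a), call. = FALSE)
    sum(c(PFA = pfa, MI = mi, placebo = 0)[toks])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Value resource-use events against a tariff table
#'
#' Applies each subcategory's valuation rule to every event and aggregates
#' costs by participant, 6-month period and component category.
#'
#' @param events data frame of events with columns `id`, `period_index`,
#'   `category`, `subcategory`, `quantity`, and where required `days` and
#'   `duration_days`.
#' @param tariffs a [tariff_table()]; every subcategory present in `events`
#'   must have a rule.
#' @param seed integer seed for the gamma-sampled components.
#' @return data frame (`id`, `period_index`, `category`, `cost`) with one row
#'   per participant x period x category that has any valued event. An empty
#'   event list yields a zero-row frame.
#' @export
value_events <- function(events, tariffs, seed = 1L) {
  needed <- unique(events$subcategory)
  missing_rules <- setdiff(needed, tariffs$rules$subcategory)
  if (length(missing_rules))
    stop("no tariff rule for subcategory: ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  if (nrow(events) && any(events$quantity < 0))
    stop("negative event quantity", call. = FALSE)
  if (!nrow(events)) {
    return(data.frame(id = integer(), period_index = integer(),
                      category = character(), cost = numeric()))
  }
  r <- tariffs$rules[match(events$subcategory, tariffs$rules$subcategory), ]
  cost <- numeric(nrow(events))
  fx <- r$rule == "fixed_tariff"
  cost[fx] <- events$quantity[fx] * r$unit_cost[fx]
  pd <- r$rule == "per_diem"
  cost[pd] <- events$quantity[pd] * events$days[pd] * r$per_diem_rate[pd]
  dd <- r$rule == "ddd_drug"
  cost[dd] <- events$quantity[dd] * r$price_per_unit[dd] * r$ddd_per_day[dd] *
    events$duration_days[dd]
  gm <- which(r$rule == "gamma_sampled")
  if (length(gm)) {
    set.seed(seed)
    # one gamma draw per unit of quantity, summed back to the event
    q <- as.integer(round(events$quantity[gm]))
    draws <- stats::rgamma(sum(q), shape = rep(r$gamma_shape[gm], q),
                           scale = rep(r$gamma_scale[gm], q))
    cost[gm] <- rowsum(c(draws, rep(0, length(gm))),
                       c(rep(seq_along(gm), q), seq_along(gm)))[, 1]
  }
  if (anyNA(cost)) stop("event attributes missing for valuation rule",
                        call. = FALSE)
  agg <- stats::aggregate(cost,
                          by = list(id = events$id,
                                    period_index = events$period_index,
                                    category = events$category),
                          FUN = sum)
  names(agg)[4] <- "cost"
  agg[order(agg$id, agg$period_index, agg$category), , drop = FALSE]
}

#' Build the per-participant cost panel for a trial dataset
#'
#' Values all resource events, prices each participant's intervention by arm,
#' and assembles 3-year cumulative totals with and without the intervention.
#' The additive identity `total_with == total_without + intervention_cost`
#' holds exactly for every participant, and the placebo arm's intervention
#' cost is 0.
#'
#' @param dataset a `trial_dataset`.
#' @param tariffs a [tariff_table()].
#' @param seed seed for gamma-sampled valuations.
#' @return object of class `cost_panel`: list with `by_component` (participant
#'   x period x category costs), `totals` (per participant: arm,
#'   `total_without`, `intervention_cost`, `total_with`, `econ_missing`), and
#'   the `tariffs` used.
#' @export
cost_panel <- function(dataset, tariffs = tariff_table(), seed = 1L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  by_comp <- value_events(dataset$events, tariffs, seed = seed)
  p <- dataset$participants
  tot <- rowsum(by_comp$cost, by_comp$id)
  total_without <- rep(0, nrow(p))
  total_without[match(as.integer(rownames(tot)), p$id)] <- tot[, 1]
  iv <- intervention_cost(p$arm, tariffs)
  totals <- data.frame(
    id = p$id, arm = p$arm,
    total_without = total_without,
    intervention_cost = iv,
    total_with = total_without + iv,
    econ_missing = p$econ_missing
  )
  structure(list(by_component = by_comp, totals = totals, tariffs = tariffs),
            class = "cost_panel")
}

#' Per-participant 3-year cumulative costs
#'
#' Sums all component costs over the six 6-month periods, optionally adding
#' the arm's intervention cost. Totals of participants flagged as missing
#' economic data are returned as `NA` when `mask_missing` is set, which is
#' how downstream imputation receives them.
#'
#' @param panel a [cost_panel()].
#' @param include_intervention add the intervention cost?
#' @param mask_missing return `NA` for participants with missing economic
#'   data?
#' @return named numeric vector of EUR totals, names = participant ids.
#' @export
cumulative_costs <- function(panel, include_intervention = TRUE,
                             mask_missing = FALSE) {
  stopifnot(inherits(panel, "cost_panel"))
  t <- panel$totals
  out <- if (include_intervention) t$total_with else t$total_without
  if (mask_missing) out[t$econ_missing] <- NA_real_
  stats::setNames(out, t$id)
}

#' @export
print.cost_panel <- function(x, ...) {
  cat("Cost panel:", nrow(x$totals), "participants,",
      nrow(x$by_component), "participant-period-component cells\n")
  m <- tapply(x$totals$total_with, x$totals$arm, mean)
  cat("  mean 3-year total (with intervention), EUR:\n")
  print(round_half_up(m))
  invisible(x)
}
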
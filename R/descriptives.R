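#' Bias-corrected and accelerated (BCa) bootstrap interval for a mean
#'
#' Nonparametric bootstrap interval for the mean of `values` with the
#' standard BCa corrections: the bias-correction constant
#' `z0 = qnorm(m / B)`, with `m` the number of bootstrap means below the
#' sample mean, and the acceleration
#' `a = sum(d_i^3) / (6 * (sum(d_i^2))^{3/2})`, where `d_i` are deviations of
#' the jackknife leave-one-out means from their average. The adjusted
#' percentiles are then read off the bootstrap distribution of the mean.
#'
#' @param values numeric sample (n >= 2).
#' @param B number of bootstrap resamples (>= 200).
#' @param alpha two-sided error level; 0.05 gives a 95% interval.
#' @param seed integer seed for the resampling.
#' @return list with `mean`, `lo`, `hi`, `z0`, `a`, and `degenerate` (TRUE
#'   when all values are identical, in which case the interval collapses to
#'   the common value and the acceleration is set to 0).
#' @export
bca_interval <- function(values, B = 2000, alpha = 0.05, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 non-missing values", call. = FALSE)
  if (B < 200) stop("B must be >= 200", call. = FALSE)
  theta <- mean(values)
  if (all(values == values[1])) {
    return(list(mean = theta, lo = theta, hi = theta, z0 = 0, a = 0,
                degenerate = TRUE))
  }
  set.seed(seed)
  boots <- rowMeans(matrix(sample(values, n * B, replace = TRUE), nrow = B))
  prop <- sum(boots < theta) / B
  # guard against a degenerate empirical proportion of 0 or 1
  prop <- min(max(prop, 1 / B), 1 - 1 / B)
  z0 <- stats::qnorm(prop)
  # jackknife acceleration
  jack <- (sum(values) - values) / (n - 1)
  d <- mean(jack) - jack
  denom <- 6 * sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / denom
  zl <- stats::qnorm(alpha / 2)
  zu <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  q <- unname(stats::quantile(boots, probs = c(a1, a2), type = 7))
  list(mean = theta, lo = q[1], hi = q[2], z0 = z0, a = a, degenerate = FALSE)
}

#' Kruskal-Wallis rank-sum comparison across groups
#'
#' Global nonparametric comparison of k groups: the rank-based H statistic
#' with mid-rank tie correction, referred to a chi-square distribution with
#' k - 1 degrees of freedom. When every observation is identical the test is
#' degenerate; H is reported as 0 with p = 1 and a flag.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   nonempty).
#' @return list with `H`, `p`, `df`, `degenerate`.
#' @export
kw_test <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0))
    stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (all(x == x[1])) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, degenerate = TRUE))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Summarize cost components per arm with BCa intervals
#'
#' Reproduces the descriptive cost-table machinery of a trial-based economic
#' evaluation: per arm and component, the mean 3-year event frequency and the
#' mean 3-year cost per participant with its BCa 95% bootstrap interval,
#' plus a global Kruskal-Wallis p-value per component across the four arms.
#' Restricted to complete cases: participants with economic data and an
#' observed final cognitive visit. Totals with and without the intervention
#' and annualized totals (cumulative / horizon) are included.
#'
#' @param panel a [cost_panel()].
#' @param dataset the `trial_dataset` the panel was built from.
#' @param B bootstrap resamples for the BCa intervals.
#' @param seed integer seed.
#' @return object of class `cost_summary`: data frame with columns
#'   `component`, `arm`, `n`, `freq_mean`, `cost_mean`, `cost_lo`, `cost_hi`,
#'   `kw_H`, `kw_p`, `degenerate`; complete-case ids in
#'   `attr(, "complete_ids")`. Arms with fewer than 2 complete cases are
#'   marked unavailable (`NA` summaries).
#' @export
summarize_costs <- function(panel, dataset, B = 2000, seed = 1L) {
  stopifnot(inherits(panel, "cost_panel"), inherits(dataset, "trial_dataset"))
  p <- dataset$participants
  final_m <- max(dataset$config$cognitive_spec$visit_months)
  has_final <- p$id %in% dataset$cognition$id[dataset$cognition$visit_month == final_m]
  cc <- p$id[!p$econ_missing & has_final]

  ev <- dataset$events[dataset$events$id %in% cc, , drop = FALSE]
  comp <- panel$by_component[panel$by_component$id %in% cc, , drop = FALSE]
  tot <- panel$totals[panel$totals$id %in% cc, , drop = FALSE]
  arms <- levels(p$arm)
  categories <- unique(panel$tariffs$rules$category)
  horizon <- panel$tariffs$horizon_years

  cell <- function(ids, arm, values, freqs, component, seed_off) {
    idx <- ids %in% tot$id[tot$arm == arm]
    v <- values[idx]
    if (length(v) < 2) {
      return(data.frame(component = component, arm = arm, n = length(v),
                        freq_mean = NA, cost_mean = NA, cost_lo = NA,
                        cost_hi = NA, degenerate = NA))
    }
    ci <- bca_interval(v, B = B, seed = derive_seed(seed, seed_off))
    data.frame(component = component, arm = arm, n = length(v),
               freq_mean = if (is.null(freqs)) NA else mean(freqs[idx]),
               cost_mean = ci$mean, cost_lo = ci$lo, cost_hi = ci$hi,
               degenerate = ci$degenerate)
  }

  per_participant <- function(df, value_col) {
    out <- rep(0, length(cc))
    if (nrow(df)) {
      s <- rowsum(df[[value_col]], df$id)
      out[match(as.integer(rownames(s)), cc)] <- s[, 1]
    }
    out
  }

  rows <- list(); kws <- list(); off <- 0L
  for (cat_i in categories) {
    cost_i <- per_participant(comp[comp$category == cat_i, ], "cost")
    freq_i <- per_participant(ev[ev$category == cat_i, ], "quantity")
    kw <- kw_test(split(cost_i, tot$arm[match(cc, tot$id)]))
    for (a in arms) {
      off <- off + 1L
      rows[[length(rows) + 1L]] <- cell(cc, a, cost_i, freq_i, cat_i, off)
    }
    kws[[cat_i]] <- kw
  }
  specials <- list(
    intervention = tot$intervention_cost,
    total_without = tot$total_without,
    total_with = tot$total_with,
    annualized_total = tot$total_with / horizon
  )
  for (nm in names(specials)) {
    vals <- specials[[nm]]
    kw <- kw_test(split(vals, tot$arm))
    for (a in arms) {
      off <- off + 1L
      rows[[length(rows) + 1L]] <- cell(tot$id, a, vals, NULL, nm, off)
    }
    kws[[nm]] <- kw
  }
  out <- do.call(rbind, rows)
  out$kw_H <- vapply(kws[out$component], `[[`, 1, "H")
  out$kw_p <- vapply(kws[out$component], `[[`, 1, "p")
  rownames(out) <- NULL
  structure(out, complete_ids = cc, class = c("cost_summary", "data.frame"))
}

#' @export
print.cost_summary <- function(x, ...) {
  cat("Complete-case cost summary (", length(attr(x, "complete_ids")),
      " participants)\n", sep = "")
  y <- as.data.frame(x)
  for (col in c("cost_mean", "cost_lo", "cost_hi"))
    y[[col]] <- round_half_up(y[[col]])
  y$freq_mean <- round(y$freq_mean, 2)
  y$kw_p <- signif(y$kw_p, 2)
  y$kw_H <- round(y$kw_H, 2)
  y$degenerate <- NULL
  print(y, row.names = FALSE)
  invisible(x)
}

#' Baseline characteristics table with global tests
#'
#' Arm-by-arm baseline description: mean (SD) with a Kruskal-Wallis p-value
#' for continuous covariates, n (%) with a chi-square p-value for
#' categorical ones.
#'
#' @param dataset a `trial_dataset`.
#' @return data frame with one row per covariate level and arm columns, plus
#'   a `p` column (test named in `test`).
#' @export
baseline_table <- function(dataset) {
  p <- dataset$participants
  arms <- levels(p$arm)
  rows <- list()
  cont <- function(x, label) {
    m <- tapply(x, p$arm, mean); s <- tapply(x, p$arm, stats::sd)
    kw <- kw_test(split(x, p$arm))
    cells <- sprintf("%.1f (%.1f)", m, s)
    data.frame(covariate = label, level = "",
               stats::setNames(as.data.frame(t(cells)), arms),
               test = "kruskal-wallis", p = kw$p, check.names = FALSE)
  }
  catg <- function(x, label) {
    tb <- table(x, p$arm)
    pv <- tryCatch(stats::chisq.test(tb)$p.value, warning = function(w)
      suppressWarnings(stats::chisq.test(tb)$p.value))
    pct <- prop.table(tb, 2) * 100
    do.call(rbind, lapply(rownames(tb), function(l) {
      cells <- sprintf("%d (%.1f)", tb[l, arms], pct[l, arms])
      data.frame(covariate = label, level = l,
                 stats::setNames(as.data.frame(t(cells)), arms),
                 test = "chi-square", p = pv, check.names = FALSE)
    }))
  }
  rows$age <- cont(p$age_years, "age_years")
  rows$med <- cont(p$n_medical_conditions, "n_medical_conditions")
  rows$gender <- catg(p$gender, "gender")
  rows$frailty <- catg(p$frailty, "frailty")
  rows$edu <- catg(p$education, "education")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
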
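#' Fit the full trial-based cost-effectiveness analysis
#'
#' The package's central estimator. From a (possibly incomplete) trial
#' dataset it runs the whole analysis chain: payer-perspective costing from
#' the tariff table; composite cognitive Z scores and their 36-month
#' changes; predictive-mean-matching multiple imputation of missing 3-year
#' cumulative costs (base case) or complete-case restriction (sensitivity
#' mode); gamma/log-link GLM cost adjustment with marginal standardization,
#' pooled by Rubin's rules; linear mixed-model effectiveness contrasts;
#' point ICERs with CE-plane quadrants; a stratified nonparametric bootstrap
#' of the (delta cost, delta effect) pairs; 95% confidence ellipses; and
#' the cost-effectiveness acceptability curve with the probability of
#' cost-effectiveness at the willingness-to-pay threshold.
#'
#' @param dataset a `trial_dataset` (after [apply_missingness()] for the
#'   base case; a complete dataset behaves like `mode = "complete_case"`
#'   with no missing data).
#' @param tariffs a [tariff_table()].
#' @param mode `"imputed"` (base case) or `"complete_case"` (sensitivity
#'   analysis restricted to participants with observed economic data and a
#'   final cognitive visit).
#' @param effect_unit `"z"` (Z points; default) or `"binary"` (percentage of
#'   participants without cognitive aggravation).
#' @param B bootstrap replicates.
#' @param m,k_donors imputation parameters, see [pmm_impute()].
#' @param wtp_grid willingness-to-pay grid for the CEAC (EUR per effect
#'   unit).
#' @param wtp_threshold headline WTP threshold.
#' @param aggravation_cutoff Z-change cutoff for the binary effect unit.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return object of class `cea_fit`; see [print.cea_fit()],
#'   [summary.cea_fit()], [coef.cea_fit()], [plot.cea_fit()].
#' @export
cea_fit <- function(dataset, tariffs = tariff_table(),
                    mode = c("imputed", "complete_case"),
                    effect_unit = c("z", "binary"),
                    B = 1000, m = 20, k_donors = 5,
                    wtp_grid = seq(0, 150000, by = 500),
                    wtp_threshold = 50000,
                    aggravation_cutoff = -0.3,
                    seed = 1L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  mode <- match.arg(mode)
  effect_unit <- match.arg(effect_unit)
  p <- dataset$participants
  placebo <- dataset$config$placebo
  panel <- cost_panel(dataset, tariffs, seed = derive_seed(seed, 11L))

  zp <- composite_z(dataset$cognition)
  changes <- z_change(zp, ids = p$id)
  z0 <- zp$z[zp$visit_month == attr(zp, "baseline_month")]
  z0 <- z0[match(p$id, zp$id[zp$visit_month == attr(zp, "baseline_month")])]

  covars <- data.frame(
    age_tercile = tercile(p$age_years),
    gender = p$gender,
    arm = stats::relevel(p$arm, ref = placebo),
    frailty = p$frailty,
    med_tercile = tercile(p$n_medical_conditions)
  )
  covars_glm <- cbind(covars,
                      z0_tercile = tercile(z0))

  y_without <- cumulative_costs(panel, include_intervention = FALSE,
                                mask_missing = TRUE)
  iv <- panel$totals$intervention_cost
  completed <- NULL
  if (mode == "imputed" && anyNA(y_without)) {
    completed <- pmm_impute(y_without, covars, m = m, k_donors = k_donors,
                            seed = derive_seed(seed, 12L))
    cost_with <- completed$imputations + iv   # additive identity per imputation
    glm_input <- structure(list(imputations = cost_with,
                                missing = completed$missing, m = m,
                                k_donors = k_donors),
                           class = "completed_datasets")
    keep <- rep(TRUE, nrow(p))
  } else {
    keep <- !is.na(y_without) & !is.na(changes)
    glm_input <- (y_without + iv)[keep]
  }

  mixed <- fit_z_mixed(zp, p)
  cov_used <- if (mode == "imputed" && !is.null(completed)) covars_glm
              else covars_glm[keep, , drop = FALSE]
  increments <- adjusted_increments(glm_input, cov_used, mixed,
                                    reference = placebo)

  if (effect_unit == "binary") {
    pct <- tapply(changes, p$arm, function(ch) {
      ch <- ch[!is.na(ch)]
      if (!length(ch)) return(NA_real_)
      100 * mean(ch > aggravation_cutoff)
    })
    increments$delta_e <- as.numeric(pct[increments$arm] - pct[[placebo]])
    increments$delta_e_se <- NA_real_
  }
  ic <- as.data.frame(icer(increments$delta_c, increments$delta_e))
  increments <- cbind(increments, ic)

  analysis <- data.frame(id = p$id, arm = covars$arm,
                         cost = y_without + iv, z_change = changes)
  reps <- bootstrap_ce(analysis, B = B, seed = derive_seed(seed, 13L),
                       effect_unit = effect_unit,
                       cutoff = aggravation_cutoff,
                       imputations = if (!is.null(completed) && mode == "imputed")
                         completed$imputations + iv else NULL,
                       reference = placebo)
  if (mode == "complete_case") {
    analysis_cc <- analysis[keep, , drop = FALSE]
    reps <- bootstrap_ce(analysis_cc, B = B, seed = derive_seed(seed, 13L),
                         effect_unit = effect_unit,
                         cutoff = aggravation_cutoff, reference = placebo)
  }
  ell <- confidence_ellipse(reps)
  ac <- ceac(reps, wtp_grid = wtp_grid, wtp_threshold = wtp_threshold)

  structure(list(
    increments = increments, replicates = reps, ellipse = ell, ceac = ac,
    mixed = mixed, imputation = completed, panel = panel,
    effect_unit = effect_unit, mode = mode, reference = placebo,
    wtp_threshold = wtp_threshold, B = B, seed = seed,
    n = nrow(p), n_complete = sum(keep)
  ), class = "cea_fit")
}

#' @export
print.cea_fit <- function(x, ...) {
  unit <- if (x$effect_unit == "z") "Z point" else "% without aggravation"
  cat(sprintf("Trial-based cost-effectiveness analysis (%s, %s)\n",
              x$mode, unit))
  cat(sprintf("  %d participants; B = %d bootstrap replicates\n", x$n, x$B))
  y <- x$increments
  tab <- data.frame(
    arm = y$arm,
    delta_cost = round_half_up(y$delta_c),
    delta_effect = round(y$delta_e, 3),
    ICER = ifelse(y$undefined, NA, round_half_up(y$ratio)),
    quadrant = y$quadrant
  )
  print(tab, row.names = FALSE)
  at <- attr(x$ceac, "at_threshold")
  cat(sprintf("  P(cost-effective at WTP %s/unit):\n",
              format(x$wtp_threshold, big.mark = ",")))
  print(round(at, 3))
  invisible(x)
}

#' @export
summary.cea_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cea_fit")
}

#' @export
print.summary.cea_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nAdjusted increments vs", f$reference, "(SEs):\n")
  y <- f$increments
  y$delta_c <- round_half_up(y$delta_c); y$delta_c_se <- round_half_up(y$delta_c_se)
  y$delta_e <- round(y$delta_e, 3); y$delta_e_se <- round(y$delta_e_se, 3)
  print(y[, c("arm", "delta_c", "delta_c_se", "delta_e", "delta_e_se")],
        row.names = FALSE)
  cat("\nConfidence ellipses (replicate covariance):\n")
  print(as.data.frame(f$ellipse), row.names = FALSE)
  if (!is.null(f$imputation))
    cat(sprintf("\nImputation: %d of %d cost totals imputed (PMM, m = %d)\n",
                sum(f$imputation$missing), f$n, f$imputation$m))
  if (f$mixed$center_dropped)
    cat("note: center random intercept dropped (singular fit)\n")
  invisible(x)
}

#' Extract the per-arm cost-effectiveness estimates
#'
#' @param object a [cea_fit()] object.
#' @param ... unused.
#' @return matrix with one row per intervention arm and columns `delta_c`,
#'   `delta_e`, `icer`.
#' @export
coef.cea_fit <- function(object, ...) {
  y <- object$increments
  out <- cbind(delta_c = y$delta_c, delta_e = y$delta_e, icer = y$ratio)
  rownames(out) <- y$arm
  out
}

#' Plot the CE plane and acceptability curve
#'
#' Two base-graphics panels: the bootstrap replicate cloud on the
#' cost-effectiveness plane with the 95% confidence ellipses and point
#' estimates, and the cost-effectiveness acceptability curves with the WTP
#' threshold marked.
#'
#' @param x a [cea_fit()] object.
#' @param which `1` (CE plane), `2` (CEAC) or `1:2`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cea_fit <- function(x, which = 1:2, ...) {
  arms <- unique(x$replicates$arm)
  cols <- stats::setNames(seq_along(arms) + 1L, arms)
  if (1 %in% which) {
    r <- x$replicates
    graphics::plot(r$delta_e, r$delta_c, col = cols[r$arm], pch = 16,
                   cex = 0.3,
                   xlab = paste0("incremental effect (", x$effect_unit, ")"),
                   ylab = "incremental cost (EUR)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
    for (a in arms) {
      poly <- attr(x$ellipse, "polygons")[[a]]
      if (!is.null(poly))
        graphics::lines(poly$delta_e, poly$delta_c, col = cols[a], lwd = 2)
    }
    y <- x$increments
    graphics::points(y$delta_e, y$delta_c, pch = 3, cex = 1.4,
                     col = cols[y$arm])
    graphics::legend("topleft", legend = arms, col = cols[arms], pch = 16,
                     bty = "n")
  }
  if (2 %in% which) {
    ac <- x$ceac
    graphics::plot(range(ac$wtp), c(0, 1), type = "n",
                   xlab = "willingness to pay (EUR per effect unit)",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability", ...)
    for (a in arms) {
      d <- ac[ac$arm == a, ]
      graphics::lines(d$wtp, d$probability, col = cols[a], lwd = 2)
    }
    graphics::abline(v = x$wtp_threshold, lty = 2, col = "grey40")
    graphics::legend("bottomright", legend = arms, col = cols[arms], lwd = 2,
                     bty = "n")
  }
  invisible(x)
}
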
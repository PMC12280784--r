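#' Composite cognitive Z score
#'
#' Standardizes each of the four cognitive tests to the baseline cohort mean
#' and SD, averages them into a composite Z, and computes the change from
#' baseline to the final visit. The composite is missing whenever any
#' component is missing at that visit.
#'
#' @param cognition long-format cognition data frame (`id`, `visit_month`,
#'   one column per test).
#' @param baseline_month visit month defining the standardization cohort.
#' @return object of class `composite_z`: data frame (`id`, `visit_month`,
#'   `z`), with the per-test baseline means/SDs in attributes and the change
#'   scores retrievable with [z_change()].
#' @export
composite_z <- function(cognition, baseline_month = 0) {
  tests <- setdiff(names(cognition), c("id", "visit_month"))
  base <- cognition[cognition$visit_month == baseline_month, , drop = FALSE]
  if (!nrow(base)) stop("no baseline visit in the panel", call. = FALSE)
  mu <- vapply(tests, function(t) mean(base[[t]], na.rm = TRUE), 1)
  sd_ <- vapply(tests, function(t) stats::sd(base[[t]], na.rm = TRUE), 1)
  if (any(!is.finite(sd_)) || any(sd_ == 0))
    stop("zero baseline SD for test: ",
         paste(tests[!is.finite(sd_) | sd_ == 0], collapse = ", "),
         call. = FALSE)
  zm <- sapply(tests, function(t) (cognition[[t]] - mu[t]) / sd_[t])
  out <- data.frame(id = cognition$id, visit_month = cognition$visit_month,
                    z = rowMeans(zm))
  structure(out, baseline_mean = mu, baseline_sd = sd_,
            baseline_month = baseline_month,
            final_month = max(cognition$visit_month),
            class = c("composite_z", "data.frame"))
}

#' Change in composite Z from baseline to the final visit
#'
#' @param zpanel a [composite_z()] panel.
#' @param ids optional participant ids defining the output order; ids without
#'   both visits get `NA`.
#' @return named numeric vector of Z-point changes.
#' @export
z_change <- function(zpanel, ids = NULL) {
  b <- zpanel[zpanel$visit_month == attr(zpanel, "baseline_month"), ]
  f <- zpanel[zpanel$visit_month == attr(zpanel, "final_month"), ]
  if (is.null(ids)) ids <- unique(zpanel$id)
  ch <- f$z[match(ids, f$id)] - b$z[match(ids, b$id)]
  stats::setNames(ch, ids)
}

#' Gamma/log-link GLM for 3-year cumulative costs
#'
#' Fits the multivariable cost model used for covariate adjustment: a
#' generalized linear model with gamma-distributed response and log link, so
#' exponentiated coefficients are relative cost risks (RR). Default covariate
#' coding: age terciles, gender, arm, baseline-Z terciles and
#' medical-condition-count terciles.
#'
#' @param costs positive numeric outcome (EUR); `NA` entries are dropped.
#' @param covariates data frame of covariates aligned with `costs`; must
#'   contain `arm`.
#' @param zero_adjust add half the smallest positive cost to all costs when
#'   non-positive totals are present (off by default; the fit errors on
#'   non-positive costs otherwise).
#' @return object of class `cost_glm`: list with the `glm` fit, the RR table
#'   (`rr`, `lo`, `hi`, Wald 95%), fitted values, and the data used.
#' @export
fit_cost_glm <- function(costs, covariates, zero_adjust = FALSE) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(costs))
  keep <- !is.na(costs)
  y <- costs[keep]
  cv <- covariates[keep, , drop = FALSE]
  if (any(y <= 0)) {
    if (!zero_adjust)
      stop("non-positive costs; set `zero_adjust = TRUE` to offset them by ",
           "half the smallest positive cost", call. = FALSE)
    y <- y + min(y[y > 0]) / 2
  }
  dat <- cbind(cost = y, cv)
  fit <- stats::glm(cost ~ ., data = dat, family = stats::Gamma(link = "log"))
  if (!fit$converged) stop("gamma GLM did not converge", call. = FALSE)
  co <- summary(fit)$coefficients
  rr <- data.frame(term = rownames(co),
                   rr = exp(co[, 1]),
                   lo = exp(co[, 1] - 1.96 * co[, 2]),
                   hi = exp(co[, 1] + 1.96 * co[, 2]),
                   p = co[, 4], row.names = NULL)
  structure(list(fit = fit, rr = rr[-1, ], fitted = stats::fitted(fit),
                 data = dat), class = "cost_glm")
}

#' @export
print.cost_glm <- function(x, ...) {
  cat("Gamma/log GLM of 3-year costs (n =", nrow(x$data), ")\n")
  y <- x$rr
  y$rr <- round(y$rr, 2); y$lo <- round(y$lo, 2); y$hi <- round(y$hi, 2)
  y$p <- signif(y$p, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Adjusted per-arm cost means from a gamma GLM
#'
#' Marginal standardization: every participant is predicted under each arm
#' in turn and the predictions averaged, giving covariate-adjusted mean
#' costs per arm over the trial's covariate distribution; differences versus
#' the reference arm are the adjusted cost increments. Standard errors come
#' from the delta method on the GLM coefficient covariance. Setting
#' `mode = "fitted"` instead averages the model's own fitted values within
#' arms (no recycling).
#'
#' @param glm_fit a [fit_cost_glm()] object.
#' @param reference reference (placebo) arm label.
#' @param mode `"marginal"` (recycled predictions, default) or `"fitted"`.
#' @return data frame per arm: `adj_mean`, `delta_c`, `delta_c_var`.
#' @export
adjusted_cost_means <- function(glm_fit, reference = "placebo",
                                mode = c("marginal", "fitted")) {
  mode <- match.arg(mode)
  fit <- glm_fit$fit
  dat <- glm_fit$data
  arms <- levels(dat$arm)
  if (mode == "fitted") {
    mns <- tapply(glm_fit$fitted, dat$arm, mean)
    out <- data.frame(arm = arms, adj_mean = as.numeric(mns[arms]))
    out$delta_c <- out$adj_mean - out$adj_mean[out$arm == reference]
    out$delta_c_var <- NA_real_
    return(out)
  }
  V <- stats::vcov(fit)
  mm <- function(a) {
    d <- dat; d$arm <- factor(a, levels = arms)
    stats::model.matrix(stats::delete.response(stats::terms(fit)), d,
                        contrasts.arg = fit$contrasts)
  }
  pred <- lapply(arms, function(a) {
    X <- mm(a)
    eta <- drop(X %*% stats::coef(fit))
    muh <- exp(eta)
    grad <- colMeans(X * muh)               # d mean / d beta
    list(mean = mean(muh), grad = grad)
  })
  names(pred) <- arms
  ref <- pred[[reference]]
  out <- do.call(rbind, lapply(arms, function(a) {
    g <- pred[[a]]$grad - ref$grad
    data.frame(arm = a, adj_mean = pred[[a]]$mean,
               delta_c = pred[[a]]$mean - ref$mean,
               delta_c_var = drop(t(g) %*% V %*% g))
  }))
  out
}

#' Linear mixed model for composite Z trajectories
#'
#' Fits the efficacy-smoothing model: fixed effects for arm, visit
#' (categorical) and their interaction; random intercepts for center and
#' participant; maximum likelihood. The adjusted 36-month effectiveness
#' contrast per arm versus placebo is the arm-by-final-visit interaction
#' coefficient, i.e. the arm difference in change from baseline. If the
#' center variance component is singular the model is refitted without the
#' center intercept and flagged.
#'
#' @param zpanel a [composite_z()] panel (or any data frame `id`,
#'   `visit_month`, `z`).
#' @param participants participant data frame with `id`, `arm`, `center_id`.
#' @return object of class `z_mixed`: list with the `lmer` fit, `contrasts`
#'   (per non-reference arm: `delta_e`, `se`, `lo`, `hi`), `center_dropped`.
#' @export
fit_z_mixed <- function(zpanel, participants) {
  d <- merge(as.data.frame(zpanel),
             participants[, c("id", "arm", "center_id")], by = "id")
  d <- d[!is.na(d$z), ]
  d$visit <- factor(d$visit_month)
  d$arm <- stats::relevel(factor(d$arm, levels = levels(participants$arm)),
                          ref = levels(participants$arm)[nlevels(participants$arm)])
  center_dropped <- FALSE
  fit <- suppressMessages(
    lme4::lmer(z ~ arm * visit + (1 | center_id) + (1 | id), data = d,
               REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    if (vc$sdcor[vc$grp == "center_id"][1] < 1e-5) {
      fit <- suppressMessages(
        lme4::lmer(z ~ arm * visit + (1 | id), data = d, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))
      center_dropped <- TRUE
    }
  }
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  final <- max(d$visit_month)
  arms <- setdiff(levels(participants$arm), levels(d$arm)[1])
  contrasts <- do.call(rbind, lapply(arms, function(a) {
    nm <- paste0("arm", a, ":visit", final)
    est <- fe[[nm]]
    se <- sqrt(V[nm, nm])
    data.frame(arm = a, delta_e = est, se = se,
               lo = est - 1.96 * se, hi = est + 1.96 * se)
  }))
  structure(list(fit = fit, contrasts = contrasts,
                 center_dropped = center_dropped,
                 reference = levels(d$arm)[1]),
            class = "z_mixed")
}

#' @export
print.z_mixed <- function(x, ...) {
  cat("Mixed model for composite Z (ML); 36-month contrasts vs",
      x$reference, "\n")
  y <- x$contrasts
  y[-1] <- lapply(y[-1], round, 3)
  print(y, row.names = FALSE)
  if (x$center_dropped) cat("note: center intercept dropped (singular)\n")
  invisible(x)
}

#' Adjusted cost and effectiveness increments per arm
#'
#' Combines the cost and effectiveness models into per-arm increments versus
#' placebo: `delta_c` is the covariate-adjusted difference in 3-year total
#' costs (intervention included), pooled over the multiply imputed datasets
#' by Rubin's rules; `delta_e` is the mixed-model 36-month composite-Z
#' contrast.
#'
#' @param completed a [pmm_impute()] result for the cost totals (with
#'   intervention), or a single numeric vector for complete-case analysis.
#' @param covariates covariate data frame aligned with the cost vector
#'   (must contain `arm`).
#' @param mixed_fit a [fit_z_mixed()] object.
#' @param reference placebo arm label.
#' @param mode passed to [adjusted_cost_means()].
#' @return data frame per non-reference arm: `delta_c`, `delta_c_se`,
#'   `delta_e`, `delta_e_se`.
#' @export
adjusted_increments <- function(completed, covariates, mixed_fit,
                                reference = "placebo", mode = "marginal") {
  if (inherits(completed, "completed_datasets")) {
    per_imp <- lapply(seq_len(completed$m), function(j) {
      g <- fit_cost_glm(completed$imputations[, j], covariates)
      adjusted_cost_means(g, reference = reference, mode = mode)
    })
    arms <- per_imp[[1]]$arm
    pooled <- do.call(rbind, lapply(setdiff(arms, reference), function(a) {
      est <- vapply(per_imp, function(x) x$delta_c[x$arm == a], 1)
      v <- vapply(per_imp, function(x) x$delta_c_var[x$arm == a], 1)
      pl <- rubin_pool(est, v)
      data.frame(arm = a, delta_c = pl$estimate, delta_c_se = pl$se)
    }))
  } else {
    g <- fit_cost_glm(completed, covariates)
    am <- adjusted_cost_means(g, reference = reference, mode = mode)
    am <- am[am$arm != reference, ]
    pooled <- data.frame(arm = am$arm, delta_c = am$delta_c,
                         delta_c_se = sqrt(am$delta_c_var))
  }
  ctr <- mixed_fit$contrasts
  pooled$delta_e <- ctr$delta_e[match(pooled$arm, ctr$arm)]
  pooled$delta_e_se <- ctr$se[match(pooled$arm, ctr$arm)]
  rownames(pooled) <- NULL
  pooled
}
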
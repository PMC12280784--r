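#' Predictive mean matching multiple imputation
#'
#' Imputes missing entries of a cost outcome by predictive mean matching
#' (PMM). Per imputation: ordinary least squares of the observed outcomes on
#' the predictor matrix gives `beta_hat`; the residual variance and
#' coefficients are drawn from their approximate Bayesian posterior
#' (scaled inverse-chi-square, then normal); predictions for missing cases
#' use the drawn coefficients while donors keep `beta_hat` predictions
#' (type-1 matching); each missing case is filled with the observed outcome
#' of one of its `k_donors` nearest-prediction donors, drawn uniformly.
#' Imputed values therefore always lie in the observed support.
#'
#' The default predictor set is the one used for cost imputation in this
#' trial family: age tercile, gender, intervention arm, frailty category,
#' and medical-history tercile.
#'
#' @param y numeric outcome with `NA` for missing entries (EUR totals).
#' @param predictors data frame of complete covariates (factors or numeric),
#'   same length as `y`.
#' @param m number of imputed datasets (>= 2).
#' @param k_donors donor-pool size (>= 1).
#' @param seed integer seed.
#' @return object of class `completed_datasets`: list with `imputations`
#'   (n x m matrix; observed entries identical across columns), `missing`
#'   (logical provenance flags), `m`, `k_donors`.
#' @export
pmm_impute <- function(y, predictors, m = 20, k_donors = 5, seed = 1L) {
  check_that(m >= 2, "m", "must be >= 2")
  check_that(k_donors >= 1, "k_donors", "must be >= 1")
  stopifnot(nrow(predictors) == length(y))
  if (anyNA(predictors)) stop("predictors must be complete", call. = FALSE)
  X <- stats::model.matrix(~ ., data = predictors)
  mis <- is.na(y)
  obs <- which(!mis)
  if (length(obs) < ncol(X) + k_donors)
    stop("fewer observed cases than predictors + k_donors", call. = FALSE)
  out <- matrix(rep(y, m), ncol = m)
  if (!any(mis)) {
    return(structure(list(imputations = out, missing = mis, m = m,
                          k_donors = k_donors), class = "completed_datasets"))
  }
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  qrX <- qr(Xo)
  beta_hat <- qr.coef(qrX, yo)
  beta_hat[is.na(beta_hat)] <- 0
  res <- yo - drop(Xo %*% beta_hat)
  nu <- length(obs) - qrX$rank
  XtX_inv <- chol2inv(qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank), drop = FALSE])
  piv <- qrX$pivot[seq_len(qrX$rank)]
  yhat_obs <- drop(Xo %*% beta_hat)
  set.seed(seed)
  for (j in seq_len(m)) {
    sigma2 <- sum(res^2) / stats::rchisq(1, df = nu)
    b <- beta_hat
    L <- chol(XtX_inv)
    b[piv] <- beta_hat[piv] +
      sqrt(sigma2) * drop(crossprod(L, stats::rnorm(length(piv))))
    yhat_mis <- drop(X[mis, , drop = FALSE] %*% b)
    for (i in seq_along(yhat_mis)) {
      dist <- abs(yhat_obs - yhat_mis[i])
      donors <- order(dist)[seq_len(k_donors)]
      out[which(mis)[i], j] <- yo[sample(donors, 1L)]
    }
  }
  structure(list(imputations = out, missing = mis, m = m, k_donors = k_donors),
            class = "completed_datasets")
}

#' @export
print.completed_datasets <- function(x, ...) {
  cat("Multiply imputed outcome:", nrow(x$imputations), "cases,",
      sum(x$missing), "imputed,", x$m, "imputations (PMM, k =",
      x$k_donors, "donors)\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance =
#' within-imputation mean + (1 + 1/m) x between-imputation variance; the
#' confidence interval uses a t reference with Barnard-Rubin adjusted
#' degrees of freedom (reducing to the classical Rubin df when the
#' complete-data df is infinite).
#'
#' @param estimates numeric vector of m per-imputation estimates.
#' @param variances numeric vector of m per-imputation (squared-SE)
#'   variances.
#' @param alpha two-sided error level.
#' @param dfcom complete-data degrees of freedom (Inf for the classical
#'   formula).
#' @return list with `estimate`, `within`, `between`, `total_variance`, `se`,
#'   `df`, `lo`, `hi`, `m`.
#' @export
rubin_pool <- function(estimates, variances, alpha = 0.05, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2) stop("need m >= 2 imputations", call. = FALSE)
  if (length(variances) != m) stop("mismatched lengths", call. = FALSE)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  t_var <- ubar + (1 + 1 / m) * b
  if (b == 0) {
    df <- if (is.finite(dfcom)) dfcom else Inf
  } else {
    r <- (1 + 1 / m) * b / ubar
    df_old <- (m - 1) * (1 + 1 / r)^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * ubar / t_var
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  }
  tc <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else
    stats::qnorm(1 - alpha / 2)
  se <- sqrt(t_var)
  list(estimate = qbar, within = ubar, between = b, total_variance = t_var,
       se = se, df = df, lo = qbar - tc * se, hi = qbar + tc * se, m = m)
}

#' Hausman-type attrition-bias check
#'
#' Compares a complete-case estimator with the imputation-based estimator of
#' the same parameter vector through the quadratic form
#' `d' (V_cc - V_mi)^-1 d`, `d` the difference of the estimates, referred to
#' chi-square with df = rank of the variance difference. Under
#' missing-at-random both estimators are consistent and the statistic is
#' small; systematic divergence signals attrition bias. A non-positive
#' -definite variance difference is handled with the Moore-Penrose
#' generalized inverse and flagged.
#'
#' @param est_cc,est_mi numeric parameter vectors (same length).
#' @param v_cc,v_mi their variance-covariance matrices (complete-case
#'   variance should dominate).
#' @return list with `statistic`, `df`, `p`, `generalized` (TRUE when the
#'   g-inverse was used).
#' @export
attrition_check <- function(est_cc, est_mi, v_cc, v_mi) {
  k <- length(est_cc)
  if (length(est_mi) != k) stop("dimension mismatch", call. = FALSE)
  v_cc <- as.matrix(v_cc); v_mi <- as.matrix(v_mi)
  if (!all(dim(v_cc) == k) || !all(dim(v_mi) == k))
    stop("dimension mismatch", call. = FALSE)
  d <- est_cc - est_mi
  V <- v_cc - v_mi
  generalized <- FALSE
  inv <- tryCatch({
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < sqrt(.Machine$double.eps) * max(abs(ev), 1)))
      stop("not positive definite")
    solve(V)
  }, error = function(e) {
    generalized <<- TRUE
    MASS::ginv(V)
  })
  df <- qr(V)$rank
  stat <- max(0, drop(t(d) %*% inv %*% d))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       generalized = generalized)
}
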
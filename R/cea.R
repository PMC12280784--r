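#' Incremental cost-effectiveness ratio with CE-plane quadrant
#'
#' `ratio = delta_c / delta_e` when the effectiveness difference is nonzero,
#' with the cost-effectiveness-plane quadrant from the signs: more costly and
#' more effective (NE) gives a meaningful ratio; cheaper and more effective
#' is `dominant`; more costly and less effective is `dominated`; cheaper and
#' less effective (SW) reports the ratio with a caution flag. A zero
#' effectiveness difference gives an undefined ratio, flagged rather than
#' raised.
#'
#' @param delta_c incremental cost (EUR).
#' @param delta_e incremental effectiveness (effect units).
#' @return list with `ratio`, `quadrant`, `caution`, `undefined`. Vectorized
#'   over its inputs (returns a data frame when length > 1).
#' @export
icer <- function(delta_c, delta_e) {
  one <- function(dc, de) {
    if (de == 0) {
      return(list(ratio = NA_real_, quadrant = if (dc >= 0) "NE" else "NW",
                  caution = FALSE, undefined = TRUE))
    }
    quadrant <- if (dc >= 0 && de > 0) "NE"
    else if (dc < 0 && de > 0) "dominant"
    else if (dc >= 0 && de < 0) "dominated"
    else "SW"
    list(ratio = dc / de, quadrant = quadrant,
         caution = identical(quadrant, "SW"), undefined = FALSE)
  }
  if (length(delta_c) == 1L) return(one(delta_c, delta_e))
  out <- Map(one, delta_c, delta_e)
  data.frame(ratio = vapply(out, `[[`, 1, "ratio"),
             quadrant = vapply(out, `[[`, "", "quadrant"),
             caution = vapply(out, `[[`, TRUE, "caution"),
             undefined = vapply(out, `[[`, TRUE, "undefined"))
}

#' Percentage of participants without cognitive aggravation
#'
#' Binary interpretation of effectiveness: a participant counts as "no
#' aggravation" when the 36-month composite-Z change is strictly greater
#' than the cutoff (default -0.3 Z points, the minimum clinically
#' significant decline predicting dementia; a change of exactly -0.3 counts
#' as aggravation).
#'
#' @param changes numeric Z-change vector (`NA` ignored).
#' @param cutoff decline threshold in Z points.
#' @return percentage in \[0, 100\].
#' @export
binary_effectiveness <- function(changes, cutoff = -0.3) {
  changes <- changes[!is.na(changes)]
  if (!length(changes)) stop("all change scores missing", call. = FALSE)
  100 * mean(changes > cutoff)
}

#' Bootstrap replicates of incremental cost and effectiveness
#'
#' Nonparametric bootstrap of the (delta cost, delta effect) pairs per
#' intervention arm versus placebo: participants are resampled with
#' replacement within arms (stratified, preserving the design), and the
#' increments recomputed per resample. The default fast mode recomputes
#' arm-mean differences; `mode = "adjusted"` refits the gamma cost GLM with
#' marginal standardization per resample (effectiveness stays on resampled
#' mean changes). When a multiply imputed cost outcome is supplied, the
#' replicates cycle through the imputed datasets so that between-imputation
#' uncertainty propagates into the cloud.
#'
#' @param analysis data frame with one row per participant: `id`, `arm`,
#'   `cost` (3-year total with intervention; may contain `NA` only if
#'   `imputations` is given), `z_change`, and the adjustment covariates when
#'   `mode = "adjusted"`.
#' @param B number of replicates.
#' @param seed integer seed.
#' @param effect_unit `"z"` (Z points) or `"binary"` (percentage without
#'   aggravation).
#' @param cutoff aggravation cutoff for `effect_unit = "binary"`.
#' @param imputations optional n x m matrix of completed cost outcomes.
#' @param mode `"means"` (default) or `"adjusted"`.
#' @param reference placebo arm label.
#' @return object of class `ce_replicates`: data frame (`arm`, `b`,
#'   `delta_c`, `delta_e`) with `effect_unit` and `seed` attributes.
#' @export
bootstrap_ce <- function(analysis, B = 1000, seed = 1L,
                         effect_unit = c("z", "binary"), cutoff = -0.3,
                         imputations = NULL, mode = c("means", "adjusted"),
                         reference = "placebo") {
  effect_unit <- match.arg(effect_unit)
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  arms <- levels(analysis$arm)
  others <- setdiff(arms, reference)
  idx_by_arm <- split(seq_len(nrow(analysis)), analysis$arm)
  if (any(vapply(idx_by_arm, length, 1L) == 0))
    stop("an arm has no participants", call. = FALSE)
  set.seed(seed)
  eff <- function(ch) {
    ch <- ch[!is.na(ch)]
    if (effect_unit == "z") mean(ch) else 100 * mean(ch > cutoff)
  }
  rows <- vector("list", B)
  m <- if (is.null(imputations)) 1L else ncol(imputations)
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_arm, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    d <- analysis[take, , drop = FALSE]
    d$cost_b <- if (is.null(imputations)) d$cost
      else imputations[take, ((b - 1L) %% m) + 1L]
    if (mode == "adjusted") {
      g <- fit_cost_glm(d$cost_b, d[, setdiff(names(d),
             c("id", "cost", "cost_b", "z_change")), drop = FALSE])
      am <- adjusted_cost_means(g, reference = reference, mode = "fitted")
      dc <- stats::setNames(am$delta_c, am$arm)[others]
    } else {
      mc <- tapply(d$cost_b, d$arm, mean, na.rm = TRUE)
      dc <- mc[others] - mc[[reference]]
    }
    me <- tapply(d$z_change, d$arm, eff)
    de <- unlist(me[others]) - me[[reference]]
    rows[[b]] <- data.frame(arm = others, b = b, delta_c = as.numeric(dc),
                            delta_e = as.numeric(de))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, effect_unit = effect_unit, seed = seed, reference = reference,
            class = c("ce_replicates", "data.frame"))
}

#' Bootstrap confidence ellipse of the CE-plane cloud
#'
#' For each arm's replicates, the ellipse of points x satisfying
#' `(x - mu)' Sigma^-1 (x - mu) <= qchisq(level, 2)`, with `mu` the
#' replicate means and `Sigma` the replicate covariance of
#' (delta_e, delta_c). Returns the parameters and a polygon for plotting.
#'
#' @param reps a [bootstrap_ce()] object (B >= 10).
#' @param level coverage level.
#' @param n_points polygon resolution.
#' @return data frame of class `ce_ellipse`, one row per arm: center, the
#'   covariance entries, `radius2`, `degenerate`; polygons in
#'   `attr(, "polygons")` (list of data frames `delta_e`, `delta_c`).
#' @export
confidence_ellipse <- function(reps, level = 0.95, n_points = 100L) {
  stopifnot(inherits(reps, "ce_replicates"))
  if (max(reps$b) < 10) stop("need B >= 10 replicates", call. = FALSE)
  r2 <- stats::qchisq(level, df = 2)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circle <- rbind(cos(theta), sin(theta))
  polys <- list()
  rows <- lapply(split(reps, reps$arm), function(d) {
    if (!nrow(d)) return(NULL)
    X <- cbind(d$delta_e, d$delta_c)
    mu <- colMeans(X)
    S <- stats::cov(X)
    degenerate <- qr(S)$rank < 2 || det(S) <= 0
    if (!degenerate) {
      R <- chol(S)
      pts <- sweep(sqrt(r2) * t(circle) %*% R, 2, mu, "+")
      polys[[as.character(d$arm[1])]] <<-
        data.frame(delta_e = pts[, 1], delta_c = pts[, 2])
    }
    data.frame(arm = as.character(d$arm[1]), center_e = mu[1], center_c = mu[2],
               var_e = S[1, 1], var_c = S[2, 2], cov_ec = S[1, 2],
               radius2 = r2, level = level, degenerate = degenerate)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  structure(out, polygons = polys, class = c("ce_ellipse", "data.frame"))
}

# internal: ellipse polygon transform uses X = mu + sqrt(r2) * circle' %*% chol(S)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` on the grid, the probability
#' that the intervention is cost-effective: the fraction of bootstrap
#' replicates with positive net monetary benefit
#' `lambda * delta_e - delta_c > 0`.
#'
#' @param reps a [bootstrap_ce()] object.
#' @param wtp_grid nonempty numeric grid of willingness-to-pay thresholds
#'   (EUR per effect unit, >= 0).
#' @param wtp_threshold headline threshold reported alongside the curve.
#' @return data frame of class `ceac` (`arm`, `wtp`, `probability`), with the
#'   per-arm probability at `wtp_threshold` in `attr(, "at_threshold")`.
#' @export
ceac <- function(reps, wtp_grid = seq(0, 150000, by = 500),
                 wtp_threshold = 50000) {
  stopifnot(inherits(reps, "ce_replicates"))
  if (!length(wtp_grid)) stop("empty WTP grid", call. = FALSE)
  if (any(wtp_grid < 0)) stop("WTP thresholds must be >= 0", call. = FALSE)
  prob_at <- function(d, lambda)
    vapply(lambda, function(l) mean(l * d$delta_e - d$delta_c > 0), 1)
  by_arm <- split(reps, reps$arm)
  by_arm <- by_arm[vapply(by_arm, nrow, 1L) > 0]
  out <- do.call(rbind, lapply(by_arm, function(d)
    data.frame(arm = d$arm[1], wtp = wtp_grid,
               probability = prob_at(d, wtp_grid))))
  at <- vapply(by_arm, prob_at, 1, lambda = wtp_threshold)
  rownames(out) <- NULL
  structure(out, at_threshold = at, wtp_threshold = wtp_threshold,
            class = c("ceac", "data.frame"))
}
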
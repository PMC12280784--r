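#' Round half away from zero
#'
#' Commercial rounding used for all euro values printed in report tables:
#' ties go away from zero (`round_half_up(0.5) == 1`), unlike base R's
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tercile coding of a numeric covariate
#'
#' Cuts `x` at its empirical terciles (computed on non-missing values of the
#' observed marginal distribution); ties on a cut point go to the lower
#' tercile. Used to code age, medical-history counts and baseline Z scores
#' the way multivariable cost models in trial-based economic evaluations
#' typically do.
#'
#' @param x numeric vector.
#' @param labels optional length-3 labels; default `T1 < T2 < T3`.
#' @return factor with three ordered levels (fewer if `x` is too discrete to
#'   support three distinct cut points).
#' @export
tercile <- function(x, labels = c("T1", "T2", "T3")) {
  q <- stats::quantile(x, probs = c(1 / 3, 2 / 3), na.rm = TRUE, type = 7)
  # ties to the lower tercile: intervals are (-Inf, q1], (q1, q2], (q2, Inf)
  brk <- unique(c(-Inf, q, Inf))
  f <- cut(x, breaks = brk, include.lowest = TRUE, right = TRUE)
  levels(f) <- labels[seq_along(levels(f))]
  f
}

# internal: stop with the offending field named, for config validation
check_that <- function(ok, field, msg) {
  if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# internal: derive a stream-specific seed from a base seed, kept within
# 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
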
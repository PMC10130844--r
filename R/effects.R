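# Cumulative exposure-response curves, minimum-risk temperature, cumulative
# odds ratios and subgroup heterogeneity.

#' Cumulative exposure-response curve over the lag window
#'
#' For each grid temperature t the contrast vector places the spline
#' difference ns(t) - ns(reference) in every lag block (the integer-lag
#' cumulative contrast); any extra covariate columns in the fit (e.g. the
#' humidity adjustment) get zero contrast.  The cumulative log odds ratio is
#' c(t)' beta and its standard error sqrt(c(t)' Sigma c(t)).
#'
#' @param fit A converged `cc_fit` (from [fit_conditional_logistic()]).
#' @param spec The `crossbasis_spec` used for the fit (defaults to the one
#'   recorded on the fit).
#' @param grid Ascending temperatures (degrees F) at which to evaluate.
#' @param reference Reference temperature (degrees F).
#' @return An `erc` data frame with columns `grid`, `cum_log_or`, `se` and
#'   attributes `reference`, `mrt` (NA until [find_mrt()]), `spec`.
#' @export
exposure_response_curve <- function(fit, spec = attr(fit, "spec"), grid,
                                    reference) {
  stopifnot(inherits(fit, "cc_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; no curve computed")
  stopifnot(inherits(spec, "crossbasis_spec"))
  if (reference < spec$spline$boundary_knots[1] ||
      reference > spec$spline$boundary_knots[2] ||
      min(grid) < spec$spline$boundary_knots[1] - 1e-9 ||
      max(grid) > spec$spline$boundary_knots[2] + 1e-9)
    warning("evaluating the spline outside its boundary knots (linear tail)")
  n_lag <- spec$lag_max - spec$lag_min + 1L
  ncb <- spec$spline$df * n_lag
  p <- length(fit$beta)
  if (p < ncb) stop("fit has fewer columns than the cross-basis")
  bdiff <- ns_basis(grid, spec$spline) -
    matrix(ns_basis(reference, spec$spline), nrow = length(grid),
           ncol = spec$spline$df, byrow = TRUE)
  C <- matrix(0, length(grid), p)
  for (l in seq_len(n_lag))
    C[, (l - 1L) * spec$spline$df + seq_len(spec$spline$df)] <- bdiff
  cum_log_or <- drop(C %*% fit$beta)
  se <- sqrt(pmax(rowSums((C %*% fit$cov) * C), 0))
  out <- data.frame(grid = grid, cum_log_or = cum_log_or, se = se)
  attr(out, "reference") <- reference
  attr(out, "mrt") <- NA_real_
  attr(out, "spec") <- spec
  class(out) <- c("erc", "data.frame")
  out
}

#' Minimum-risk temperature and MRT-referenced curve
#'
#' Locates the temperature minimizing the cumulative log odds ratio over a
#' fine grid spanning the observed exposure range (ties broken toward the
#' lowest temperature), then recomputes the curve referenced at that MRT.
#' The minimizer is invariant to the provisional reference because
#' re-referencing shifts the whole curve by a constant.
#'
#' @param fit A converged `cc_fit`.
#' @param spec The fit's `crossbasis_spec`.
#' @param range Length-2 observed exposure range (degrees F) to search.
#' @param step Grid resolution in degrees F (default 0.1).
#' @return An `erc` curve referenced at the MRT, with attribute `mrt`.
#' @export
find_mrt <- function(fit, spec = attr(fit, "spec"), range, step = 0.1) {
  stopifnot(length(range) == 2L, range[1] <= range[2], step > 0)
  grid <- seq(range[1], range[2], by = step)
  if (grid[length(grid)] < range[2]) grid <- c(grid, range[2])
  provisional <- exposure_response_curve(fit, spec, grid, reference = grid[1])
  mrt <- grid[which.min(provisional$cum_log_or)]  # first minimum = lowest temp
  out <- exposure_response_curve(fit, spec, grid, reference = mrt)
  attr(out, "mrt") <- mrt
  out
}

#' Cumulative odds ratio at a temperature, with Wald interval
#'
#' Exponentiates the cumulative log odds ratio at `t` (linearly interpolated
#' on the curve grid) and its normal-theory confidence limits
#' exp(log-OR +/- z * se).
#'
#' @param curve An `erc` curve.
#' @param t Temperature (degrees F), inside the curve grid.
#' @param level Confidence level (default 0.95).
#' @return Named numeric: `or`, `ci_low`, `ci_high`.
#' @export
cumulative_or <- function(curve, t, level = 0.95) {
  stopifnot(inherits(curve, "erc"), level > 0, level < 1, length(t) == 1L)
  if (t < min(curve$grid) - 1e-9 || t > max(curve$grid) + 1e-9)
    stop("temperature ", t, " outside the curve grid")
  lo <- stats::approx(curve$grid, curve$cum_log_or, xout = t, rule = 1)$y
  se <- stats::approx(curve$grid, curve$se, xout = t, rule = 1)$y
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(lo), ci_low = exp(lo - z * se), ci_high = exp(lo + z * se))
}

#' Cochran's Q homogeneity test across subgroup estimates
#'
#' Fixed-effect weights w = 1/se^2, pooled estimate sum(w theta)/sum(w),
#' Q = sum w (theta - pooled)^2, compared to a chi-square with k - 1 degrees
#' of freedom.
#'
#' @param log_or Subgroup log odds ratios (length >= 2).
#' @param se Their standard errors (all > 0).
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(log_or, se) {
  if (length(log_or) < 2L) stop("need at least two estimates")
  if (length(se) != length(log_or)) stop("log_or and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  Q <- sum(w * (log_or - pooled)^2)
  df <- length(log_or) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}
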
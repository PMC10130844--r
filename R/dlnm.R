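# Natural cubic spline exposure basis and integer-lag cross-basis.
#
# The basis uses the truncated-power construction with natural (linear-tail)
# constraints: with knots k_1 < ... < k_M (boundary knots first and last,
# interior knots in between), define
#   d_j(x) = [ (x - k_j)_+^3 - (x - k_M)_+^3 ] / (k_M - k_j)
# and take columns  x,  d_1 - d_{M-1}, ..., d_{M-2} - d_{M-1}.
# This spans the natural cubic spline space without intercept: df = M - 1 =
# 1 + number of interior knots; piecewise cubic, C2 everywhere, linear beyond
# the boundary knots.  Any basis spanning the same space (e.g. a B-spline
# projection) yields the same fitted curves.

#' Natural cubic spline specification
#'
#' @param df Degrees of freedom of the (intercept-free) basis; equals
#'   1 + number of interior knots.
#' @param interior_knots Interior knot locations (degrees F), strictly
#'   increasing; length `df - 1`.
#' @param boundary_knots Length-2 vector bracketing the interior knots.
#' @return A `spline_spec` list.
#' @seealso [spline_spec_from_sample()] for the default quantile placement.
#' @export
spline_spec <- function(df = 3L, interior_knots, boundary_knots) {
  df <- as.integer(df)
  stopifnot(df >= 1L, length(boundary_knots) == 2L,
            boundary_knots[1] < boundary_knots[2])
  interior_knots <- as.numeric(interior_knots)
  if (length(interior_knots) != df - 1L)
    stop("need df - 1 = ", df - 1L, " interior knots, got ",
         length(interior_knots))
  k <- c(boundary_knots[1], interior_knots, boundary_knots[2])
  if (any(diff(k) <= 0)) stop("knots must be strictly increasing and bracketed")
  structure(list(df = df, interior_knots = interior_knots,
                 boundary_knots = as.numeric(boundary_knots)),
            class = "spline_spec")
}

#' Spline specification from an exposure sample
#'
#' Places `df - 1` interior knots at equally spaced quantiles of the sample
#' (e.g. the 33.3rd/66.7th percentiles for `df = 3`) and boundary knots at
#' the observed minimum and maximum — the conventional placement for
#' distributed-lag temperature models.  Knot locations are recorded in the
#' spec so results can be reproduced exactly.
#'
#' @param x Exposure sample (degrees F).
#' @param df Basis degrees of freedom.
#' @export
spline_spec_from_sample <- function(x, df = 3L) {
  x <- x[is.finite(x)]
  stopifnot(length(x) >= 2L)
  df <- as.integer(df)
  ik <- if (df > 1L)
    stats::quantile(x, probs = seq_len(df - 1L) / df, type = 7, names = FALSE)
  else numeric(0)
  spline_spec(df, ik, range(x))
}

#' Evaluate the natural cubic spline basis
#'
#' @param x Numeric vector of exposures (degrees F).
#' @param spec A `spline_spec`.
#' @return Matrix `length(x)` by `spec$df` (no intercept column), columns
#'   named `s1..s<df>`.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"), all(is.finite(x)))
  k <- c(spec$boundary_knots[1], spec$interior_knots, spec$boundary_knots[2])
  M <- length(k)
  out <- matrix(0, length(x), spec$df)
  out[, 1] <- x
  if (M > 2L) {
    dfun <- function(j) (pmax(x - k[j], 0)^3 - pmax(x - k[M], 0)^3) / (k[M] - k[j])
    dlast <- dfun(M - 1L)
    for (j in seq_len(M - 2L)) out[, j + 1L] <- dfun(j) - dlast
  }
  colnames(out) <- paste0("s", seq_len(spec$df))
  out
}

#' Cross-basis specification: exposure spline by integer lags
#'
#' One unconstrained copy of the exposure spline per integer lag day
#' ("integer lag functions"): total columns `df * (lag_max - lag_min + 1)`,
#' ordered lag-major (all spline columns of lag 0, then lag 1, ...).
#'
#' @param spline A `spline_spec`.
#' @param lag_min,lag_max Integer lag range in days (default 0-5).
#' @export
crossbasis_spec <- function(spline, lag_min = 0L, lag_max = 5L) {
  stopifnot(inherits(spline, "spline_spec"), lag_min <= lag_max, lag_min >= 0L)
  structure(list(spline = spline, lag_min = as.integer(lag_min),
                 lag_max = as.integer(lag_max)),
            class = "crossbasis_spec")
}

n_crossbasis_cols <- function(spec)
  spec$spline$df * (spec$lag_max - spec$lag_min + 1L)

#' Build cross-basis rows for a set of dates
#'
#' Row for date `d`, lag block `l` is `ns_basis(tmin[d - l])`; the exposure
#' series must cover every lagged date with a non-missing minimum
#' temperature.
#'
#' @param exposure A `city_series`.
#' @param dates `Date` vector (one output row per element).
#' @param spec A `crossbasis_spec`.
#' @return Matrix `length(dates)` by `df * n_lags`, columns named
#'   `lag<l>_s<j>`.
#' @export
build_crossbasis <- function(exposure, dates, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  dates <- as.Date(dates)
  lags <- spec$lag_min:spec$lag_max
  day0 <- as.integer(exposure$date[1])
  nd <- nrow(exposure)
  blocks <- vector("list", length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    idx <- as.integer(dates) - l - day0 + 1L
    idx[idx < 1L | idx > nd] <- NA_integer_
    if (anyNA(idx)) {
      d <- dates[is.na(idx)][1]
      stop("exposure series does not cover ", d - l,
           " (needed for date ", d, " at lag ", l, ")")
    }
    t <- exposure$tmin[idx]
    if (anyNA(t)) {
      d <- dates[is.na(t)][1]
      stop("exposure gap at ", d - l, " (needed for date ", d,
           " at lag ", l, ")")
    }
    b <- ns_basis(t, spec$spline)
    colnames(b) <- paste0("lag", l, "_", colnames(b))
    blocks[[i]] <- b
  }
  do.call(cbind, blocks)
}
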
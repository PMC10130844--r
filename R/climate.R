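# Citywide exposure series construction from weather-station records.
# All temperatures are degrees Fahrenheit throughout the package; the only
# Celsius conversion lives in f_to_c() for the humidity formula.

f_to_c <- function(f) (f - 32) * 5 / 9
c_to_f <- function(c) c * 9 / 5 + 32

#' Read a station record CSV
#'
#' Expects columns `station_id,date,tmin_f,tmean_f,tdew_f` with ISO-8601
#' dates; an empty cell is a missing component for that station-day.
#'
#' @param path Path to the CSV file.
#' @return A list of per-station data frames (columns `station_id`, `date`,
#'   `tmin`, `tmean`, `tdew`; temperatures in degrees F), one element per
#'   station id.
#' @export
read_station_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(station_id = "character"))
  need <- c("station_id", "date", "tmin_f", "tmean_f", "tdew_f")
  if (!all(need %in% names(raw)))
    stop("station CSV must have columns: ", paste(need, collapse = ", "))
  df <- data.frame(station_id = raw$station_id,
                   date  = as.Date(raw$date),
                   tmin  = as.numeric(raw$tmin_f),
                   tmean = as.numeric(raw$tmean_f),
                   tdew  = as.numeric(raw$tdew_f),
                   stringsAsFactors = FALSE)
  lapply(split(df, df$station_id), function(s) {
    if (anyDuplicated(s$date)) stop("duplicate dates for station ", s$station_id[1])
    s[order(s$date), , drop = FALSE]
  })
}

#' Write station records to CSV
#'
#' @param stations A list of station data frames as returned by
#'   [read_station_csv()] or [simulate_temperature()].
#' @param path Output path.
#' @export
write_station_csv <- function(stations, path) {
  df <- do.call(rbind, lapply(stations, function(s)
    data.frame(station_id = s$station_id, date = as.character(s$date),
               tmin_f = s$tmin, tmean_f = s$tmean, tdew_f = s$tdew)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

new_city_series <- function(date, tmin, tmean, rh) {
  stopifnot(!anyDuplicated(date))
  o <- order(date)
  x <- data.frame(date = date[o], tmin = tmin[o], tmean = tmean[o], rh = rh[o])
  # contiguous calendar coverage: insert explicit NA rows for absent days
  full <- seq(min(x$date), max(x$date), by = "day")
  if (length(full) != nrow(x)) {
    idx <- match(full, x$date)
    x <- data.frame(date = full, tmin = x$tmin[idx], tmean = x$tmean[idx],
                    rh = x$rh[idx])
  }
  bad <- !is.na(x$rh) & (x$rh < 0 | x$rh > 100)
  if (any(bad)) stop("relative humidity outside [0,100] on ", x$date[bad][1])
  attr(x, "gaps") <- x$date[is.na(x$tmin)]
  class(x) <- c("city_series", "data.frame")
  x
}

#' Average station series into a citywide daily exposure series
#'
#' Computes, for each calendar day, the unweighted arithmetic mean over the
#' stations reporting that day, separately for each component (daily minimum
#' temperature, mean temperature, dew point).  Relative humidity is then
#' derived from the citywide mean and dew-point temperatures.  Days on which
#' no station reports the minimum temperature are exposure gaps: they are
#' kept as `NA` rows and listed in the `"gaps"` attribute, unless `coverage`
#' is supplied, in which case a gap inside the requested range is an error.
#'
#' @param stations Non-empty list of station data frames (`date`, `tmin`,
#'   `tmean`, `tdew` in degrees F).
#' @param coverage Optional `Date` vector of length 2; require gap-free
#'   `tmin` coverage of this closed date range.
#' @return A `city_series` data frame with columns `date`, `tmin`, `tmean`,
#'   `rh` and a `"gaps"` attribute.
#' @export
average_stations <- function(stations, coverage = NULL) {
  if (length(stations) == 0) stop("empty station list")
  all_dates <- sort(unique(as.Date(unlist(lapply(stations, function(s)
    as.character(s$date))))))
  if (length(all_dates) == 0) stop("stations contain no dated records")
  days <- seq(min(all_dates), max(all_dates), by = "day")
  comp_mean <- function(component) {
    m <- vapply(stations, function(s) {
      v <- s[[component]][match(days, s$date)]
      as.numeric(v)
    }, numeric(length(days)))
    m <- matrix(m, nrow = length(days))
    rowMeans(m, na.rm = TRUE)  # NaN when no station reports
  }
  tmin  <- comp_mean("tmin");  tmin[is.nan(tmin)]   <- NA_real_
  tmean <- comp_mean("tmean"); tmean[is.nan(tmean)] <- NA_real_
  tdew  <- comp_mean("tdew");  tdew[is.nan(tdew)]   <- NA_real_
  ok <- !is.na(tmean) & !is.na(tdew)
  rh <- rep(NA_real_, length(days))
  rh[ok] <- relative_humidity(tmean[ok], tdew[ok])
  out <- new_city_series(days, tmin, tmean, rh)
  if (!is.null(coverage)) {
    want <- seq(as.Date(coverage[1]), as.Date(coverage[2]), by = "day")
    miss <- want[!(want %in% out$date) | is.na(out$tmin[match(want, out$date)])]
    if (length(miss))
      stop("exposure gap inside requested coverage: no station reports tmin on ",
           miss[1])
  }
  out
}

#' Relative humidity from mean and dew-point temperature
#'
#' Magnus-form saturation vapour pressure with coefficients 17.625 and
#' 243.04: RH = 100 * e(tdew) / e(tmean), e(T in C) =
#' exp(17.625 T / (243.04 + T)).  Inputs are in degrees F and converted
#' internally; the result is clamped to (0, 100].
#'
#' @param tmean_f,tdew_f Mean and dew-point temperature, degrees F.
#'   Vectorised; `tdew_f` must not exceed `tmean_f` (supersaturation is not
#'   modelled).
#' @return Relative humidity in percent.
#' @export
relative_humidity <- function(tmean_f, tdew_f) {
  stopifnot(is.finite(tmean_f), is.finite(tdew_f))
  if (any(tdew_f > tmean_f + 1e-9))
    stop("dew point exceeds mean temperature (supersaturation not modelled)")
  es <- function(tc) exp(17.625 * tc / (243.04 + tc))
  rh <- 100 * es(f_to_c(tdew_f)) / es(f_to_c(tmean_f))
  pmin(rh, 100)
}

# Inverse of relative_humidity for the generator: dew point (F) giving the
# requested RH at the given mean temperature.
dewpoint_from_rh <- function(tmean_f, rh_pct) {
  tc <- f_to_c(tmean_f)
  g <- log(rh_pct / 100) + 17.625 * tc / (243.04 + tc)
  c_to_f(243.04 * g / (17.625 - g))
}

#' Warm-season exposure percentile
#'
#' Quantile of the daily minimum temperature restricted to the given calendar
#' months over the whole coverage of the series, using linear interpolation
#' between order statistics (quantile type 7); the rule is recorded in the
#' `"quantile_rule"` attribute of the result.
#'
#' @param series A `city_series`.
#' @param p Quantile level in (0, 1).
#' @param months Integer calendar months to restrict to (default June-August).
#' @return Temperature in degrees F with attribute `quantile_rule`.
#' @export
exposure_percentile <- function(series, p, months = 6:8) {
  stopifnot(p > 0, p < 1)
  mo <- as.POSIXlt(series$date)$mon + 1L
  v <- series$tmin[mo %in% months & !is.na(series$tmin)]
  if (length(v) == 0) stop("no exposure values in the selected months")
  q <- stats::quantile(v, probs = p, type = 7, names = FALSE)
  attr(q, "quantile_rule") <- "type7_linear_order_statistic_interpolation"
  q
}

#' Write / read a citywide series CSV (`date,tmin_f,tmean_f,rh_pct`)
#' @param series A `city_series`.
#' @param path File path.
#' @export
write_city_csv <- function(series, path) {
  utils::write.csv(data.frame(date = as.character(series$date),
                              tmin_f = series$tmin, tmean_f = series$tmean,
                              rh_pct = series$rh),
                   path, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname write_city_csv
#' @export
read_city_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_city_series(as.Date(raw$date), as.numeric(raw$tmin_f),
                  as.numeric(raw$tmean_f), as.numeric(raw$rh_pct))
}
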
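# Synthetic warm-season study generator: citywide exposure series with the
# study's marginal moments, and encounter line lists whose daily log-rate
# carries calendar effects plus a known non-linear lag-0..5 temperature
# effect.  Everything is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults emulate the study conditions: seven warm seasons (2005-2011) of
#' daily minimum temperature with June-August mean 67.9 F and SD 5.4 F,
#' roughly 7.8 expected mental-health encounters per day across three age
#' groups (about 5,000 per simulated study), day-of-week/month/year
#' confounding switched on, and a U-shaped true temperature response
#' f(t) = a (t - vertex)^2 with vertex near 69 F distributed over lags 0-5
#' with decaying weights summing to 1 (true cumulative log OR at 76 F vs the
#' vertex = 0.004 * 49 = 0.196, OR about 1.22).  Any element can be
#' overridden via `...`.
#'
#' @param seed Integer RNG seed.
#' @param ... Named overrides of any default field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    years = 2005:2011,
    months = 6:8,
    # exposure process
    season_mean_f = 67.9, season_sd_f = 5.4,
    seasonal_amp_f = 4, seasonal_peak_doy = 198L,
    ar1_rho = 0.6, clip_f = c(45, 92),
    tmean_offset_f = 10, rh_mean = 65, rh_sd = 10,
    n_stations = 4L, station_dev_sd_f = 1.5,
    # encounter process
    n_expected_daily = c("6-11" = 1.2, "12-17" = 2.6, "18-25" = 4.0),
    dow_log = c(0.05, 0, -0.02, 0, 0.03, -0.12, -0.15),   # Mon..Sun
    month_log = c("6" = 0, "7" = 0.08, "8" = -0.05),
    year_log = NULL,   # filled below: linear trend over years
    response = list(a = 0.004, vertex = 69,
                    weights = c(0.30, 0.25, 0.20, 0.15, 0.07, 0.03)),
    effect_month_scale = c("6" = 1, "7" = 1, "8" = 1),
    sex_mix   = c(male = 0.56, female = 0.43, unknown = 0.01),
    race_mix  = c(hispanic = 0.24, nh_black = 0.35, nh_white = 0.18,
                  nh_other = 0.22, unknown = 0.01),
    payer_mix = c(commercial = 0.31, medicaid = 0.25, self_pay = 0.19,
                  other = 0.25),
    dx_mix = c(substance_use = 0.20, psychosis = 0.18, bipolar = 0.12,
               depression = 0.25, developmental = 0.05, organic = 0.02,
               other_mh = 0.18),
    suicide_ecode_rate = 0.07,
    ed_fraction = 0.72,
    frac_scheduled = 0.02,   # scheduled inpatient padding, filtered out
    frac_non_mh = 0.05       # non-mental-health padding, filtered out
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$year_log))   # default: a mild linear secular trend
    cfg$year_log <- stats::setNames(seq(-0.06, 0.06,
                                        length.out = length(cfg$years)),
                                    cfg$years)
  for (m in c("sex_mix", "race_mix", "payer_mix", "dx_mix"))
    if (abs(sum(cfg[[m]]) - 1) > 1e-8) stop(m, " must sum to 1")
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) stop("ar1_rho must be in [0, 1)")
  stopifnot(cfg$season_sd_f > 0, all(is.finite(cfg$response$weights)))
  class(cfg) <- "sim_config"
  cfg
}

sim_quad <- function(t, response) response$a * (t - response$vertex)^2

#' True cumulative log odds ratio under the generating model
#'
#' The estimand the case-crossover DLNM targets: sum over lags of
#' w_l * (f(t) - f(reference)).
#'
#' @param config A `sim_config`.
#' @param t,reference Temperatures (degrees F).
#' @export
true_cumulative_log_or <- function(config, t, reference) {
  sum(config$response$weights) *
    (sim_quad(t, config$response) - sim_quad(reference, config$response))
}

# Season dates per year: generation window (with lag lead-in) and analysis
# months.
sim_dates <- function(years, from_md = "05-20", to_md = "08-31") {
  do.call(c, lapply(years, function(y)
    seq(as.Date(sprintf("%d-%s", y, from_md)),
        as.Date(sprintf("%d-%s", y, to_md)), by = "day")))
}

#' Simulate the citywide exposure series (and station records)
#'
#' Daily minimum temperature is a seasonal sinusoid plus AR(1) Gaussian
#' noise, calibrated so the June-August marginal mean and SD equal the
#' configured values, then clipped to a physical range; coverage runs from
#' May 20 to August 31 of each simulated year (the analysis needs lags back
#' to May 27).  Mean temperature is `tmin + tmean_offset_f`; the dew point is
#' set to achieve a clipped-normal relative-humidity distribution.  Station
#' records are the city series plus zero-mean-per-day station deviations, so
#' averaging the stations reproduces the city series exactly.
#'
#' @param config A `sim_config`.
#' @param return_stations Also return the per-station records.
#' @return A `city_series`, or (if `return_stations`) a list
#'   `list(city, stations)`.
#' @export
simulate_temperature <- function(config, return_stations = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed %% 2147483647L)
  dates <- sim_dates(config$years)
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  s <- config$seasonal_amp_f *
    cos(2 * pi * (doy - config$seasonal_peak_doy) / 365)
  jja <- (lt$mon + 1L) %in% config$months
  m_s <- mean(s[jja])
  v_s <- mean((s[jja] - m_s)^2)
  noise_var <- max(config$season_sd_f^2 - v_s, 0)
  sigma <- sqrt(noise_var)
  rho <- config$ar1_rho
  z <- numeric(length(dates))
  yr <- lt$year
  for (y in unique(yr)) {
    i <- which(yr == y)
    e <- stats::rnorm(length(i))
    zz <- numeric(length(i))
    zz[1] <- sigma * e[1]
    if (length(i) > 1)
      for (k in 2:length(i))
        zz[k] <- rho * zz[k - 1] + sigma * sqrt(1 - rho^2) * e[k]
    z[i] <- zz
  }
  tmin <- config$season_mean_f + (s - m_s) + z
  tmin <- pmin(pmax(tmin, config$clip_f[1]), config$clip_f[2])
  tmean <- tmin + config$tmean_offset_f
  rh <- pmin(pmax(stats::rnorm(length(dates), config$rh_mean, config$rh_sd),
                  20), 100)
  tdew <- dewpoint_from_rh(tmean, rh)
  city <- new_city_series(dates, tmin, tmean, rh)
  if (!return_stations) return(city)
  ns <- config$n_stations
  dev <- matrix(stats::rnorm(length(dates) * ns, 0, config$station_dev_sd_f),
                ncol = ns)
  dev <- dev - rowMeans(dev)  # exact zero daily mean: averaging recovers city
  stations <- lapply(seq_len(ns), function(k) {
    td <- pmin(tdew + dev[, k], tmean + dev[, k])
    data.frame(station_id = sprintf("ST%02d", k), date = dates,
               tmin = tmin + dev[, k], tmean = tmean + dev[, k], tdew = td,
               stringsAsFactors = FALSE)
  })
  list(city = city, stations = stations)
}

#' Simulate an encounter line list
#'
#' Daily encounter counts per age group are Poisson with log-rate
#' log(baseline) + day-of-week + month + year effects +
#' scale_m(d) * sum_l w_l f(tmin[d - l]); each event receives demographics,
#' payer, a primary ICD-9 diagnosis drawn from the configured category mix,
#' a suicide E-code with the configured rate, and an ED/inpatient setting.
#' Padding records (non-mental-health diagnoses; scheduled inpatient stays)
#' are appended so the cohort filters have work to do; they carry no
#' temperature signal of their own consequence since they are filtered out.
#'
#' @param config A `sim_config`.
#' @param exposure A `city_series` covering the analysis months plus lags.
#' @return An encounter line-list data frame.
#' @export
simulate_encounters <- function(config, exposure) {
  stopifnot(inherits(config, "sim_config"), inherits(exposure, "city_series"))
  set.seed((config$seed + 1000003L) %% 2147483647L)
  days <- sim_dates(config$years, from_md = "06-01")
  lt <- as.POSIXlt(days)
  lagmat <- vapply(0:5, function(l) {
    idx <- match(days - l, exposure$date)
    if (anyNA(idx) || anyNA(exposure$tmin[idx]))
      stop("exposure coverage incomplete for simulated encounters")
    exposure$tmin[idx]
  }, numeric(length(days)))
  w <- config$response$weights
  fx <- sim_quad(lagmat, config$response)
  temp_term <- drop(fx %*% w)
  mo <- as.character(lt$mon + 1L)
  temp_term <- temp_term * unname(config$effect_month_scale[mo])
  dow <- ((lt$wday + 6L) %% 7L) + 1L   # Monday = 1
  cal <- config$dow_log[dow] + unname(config$month_log[mo]) +
    unname(config$year_log[as.character(lt$year + 1900L)])
  groups <- names(config$n_expected_daily)
  recs <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    lambda <- config$n_expected_daily[[g]] * exp(cal + temp_term)
    if (any(!is.finite(lambda)) || max(lambda) > 1e6)
      stop("encounter rate overflow: check the simulation config")
    n <- stats::rpois(length(days), lambda)
    total <- sum(n)
    if (total == 0) { recs[[g]] <- NULL; next }
    bounds <- as.integer(strsplit(groups[g], "-")[[1]])
    recs[[g]] <- data.frame(
      admit_date = rep(days, n),
      age_years = sample(bounds[1]:bounds[2], total, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, recs)
  n_ev <- nrow(ev)
  draw <- function(mix, n) sample(names(mix), n, replace = TRUE, prob = mix)
  ev$sex <- draw(config$sex_mix, n_ev)
  ev$race_eth <- draw(config$race_mix, n_ev)
  ev$payer <- draw(config$payer_mix, n_ev)
  cat_codes <- list(
    substance_use = c("291.81", "292.0", "292.89"),
    psychosis = c("295.30", "295.90", "297.1", "298.9"),
    bipolar = c("296.40", "296.80", "296.64"),
    depression = c("296.20", "296.30", "298.0"),
    developmental = c("299.80", "299.90"),
    organic = c("293.0", "294.9"),
    other_mh = c("296.90", "298.8"))
  cat <- draw(config$dx_mix, n_ev)
  ev$primary_dx <- character(n_ev)
  for (cc in unique(cat)) {
    i <- which(cat == cc)
    ev$primary_dx[i] <- sample(cat_codes[[cc]], length(i), replace = TRUE)
  }
  ev$ecodes <- ifelse(stats::runif(n_ev) < config$suicide_ecode_rate,
                      "E950.0", "")
  ev$setting <- ifelse(stats::runif(n_ev) < config$ed_fraction,
                       "ED", "inpatient")
  ev$scheduled <- FALSE
  pad <- function(frac, dx_pool, scheduled) {
    m <- stats::rpois(1, frac * n_ev)
    if (m == 0) return(NULL)
    data.frame(admit_date = sample(days, m, replace = TRUE),
               age_years = sample(6:25, m, replace = TRUE),
               sex = draw(config$sex_mix, m),
               race_eth = draw(config$race_mix, m),
               payer = draw(config$payer_mix, m),
               primary_dx = sample(dx_pool, m, replace = TRUE),
               ecodes = "",
               setting = if (scheduled) "inpatient"
                         else sample(c("ED", "inpatient"), m, replace = TRUE),
               scheduled = scheduled, stringsAsFactors = FALSE)
  }
  out <- rbind(ev,
               pad(config$frac_non_mh, c("486", "780.2", "845.00"), FALSE),
               pad(config$frac_scheduled, c("296.30", "295.90"), TRUE))
  out <- out[order(out$admit_date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a complete study
#'
#' @param config A `sim_config`.
#' @return List with `exposure` (`city_series`), `stations`, `encounters`
#'   (line list) and `truth` (the generating response and a function of
#'   (t, reference) giving the true cumulative log OR).
#' @export
simulate_study <- function(config = sim_config()) {
  tmp <- simulate_temperature(config, return_stations = TRUE)
  enc <- simulate_encounters(config, tmp$city)
  list(exposure = tmp$city, stations = tmp$stations, encounters = enc,
       truth = list(response = config$response,
                    effect_month_scale = config$effect_month_scale,
                    cum_log_or = function(t, reference)
                      true_cumulative_log_or(config, t, reference)))
}

#' Write a simulated study to disk
#'
#' Emits the station CSV and line-list CSV dialects the analysis pipeline
#' reads, plus `truth.json` with the generating parameters.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param config The `sim_config` used (recorded in `truth.json`).
#' @export
write_study <- function(study, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_station_csv(study$stations, file.path(dir, "stations.csv"))
  write_encounters_csv(study$encounters, file.path(dir, "encounters.csv"))
  truth <- list(response = study$truth$response,
                effect_month_scale = as.list(study$truth$effect_month_scale))
  if (!is.null(config)) truth$config <- unclass(config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
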
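# Synthetic-data generator: determinism, calibration, and truth.

test_that("generator outputs are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 5, years = 2005:2006)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$exposure$tmin, b$exposure$tmin)
  expect_identical(a$encounters, b$encounters)
  c2 <- simulate_temperature(sim_config(seed = 6, years = 2005:2006))
  expect_false(identical(a$exposure$tmin, c2$tmin))
})

test_that("zero noise leaves the deterministic seasonal sinusoid", {
  cfg <- sim_config(seed = 1, years = 2005, season_sd_f = 1e-9)
  # with sd ~ 0 the AR(1) noise and the sinusoid spread must both vanish
  # only when the amplitude is 0 too
  cfg0 <- sim_config(seed = 1, years = 2005, season_sd_f = 1e-9,
                     seasonal_amp_f = 0)
  s <- simulate_temperature(cfg0)
  expect_lt(max(abs(s$tmin - 67.9)), 1e-6)
  s1 <- simulate_temperature(cfg)
  lt <- as.POSIXlt(s1$date)
  doy <- lt$yday + 1
  expected <- 67.9 + 4 * (cos(2 * pi * (doy - 198) / 365) -
                          mean(cos(2 * pi * (doy[(lt$mon + 1) %in% 6:8] - 198)
                                   / 365)))
  expect_lt(max(abs(s1$tmin - expected)), 1e-4)
})

test_that("warm-season moments match the configured mean and SD", {
  # Monte-Carlo check over 200 simulated seasons against 67.9 / 5.4
  means <- numeric(200)
  sds <- numeric(200)
  for (r in 1:200) {
    s <- simulate_temperature(sim_config(seed = 9000 + r, years = 2005))
    lt <- as.POSIXlt(s$date)
    v <- s$tmin[(lt$mon + 1) %in% 6:8]
    means[r] <- mean(v)
    sds[r] <- sd(v)
  }
  se_mean <- sd(means) / sqrt(200)
  se_sd <- sd(sds) / sqrt(200)
  expect_lt(abs(mean(means) - 67.9), 3 * se_mean)
  expect_lt(abs(mean(sds) - 5.4), 3 * se_sd + 0.05)  # AR(1) short-series bias
  # physical range comparable to the observed 50-83 F span
  expect_true(all(means > 60 & means < 76))
})

test_that("null temperature weights give counts independent of temperature", {
  cfg <- mc_sim_config(seed = 17,
                       response = list(a = 0.004, vertex = 69,
                                       weights = rep(0, 6)),
                       dow_log = rep(0, 7),
                       month_log = c("6" = 0, "7" = 0, "8" = 0),
                       year_log = NULL)
  cfg$year_log <- stats::setNames(rep(0, length(cfg$years)), cfg$years)
  exposure <- simulate_temperature(cfg)
  enc <- simulate_encounters(cfg, exposure)
  days <- ccdlnm:::sim_dates(cfg$years, from_md = "06-01")
  counts <- as.numeric(table(factor(as.character(enc$admit_date),
                                    levels = as.character(days))))
  # mean daily count ~ baseline (padding adds ~7%)
  expect_lt(abs(mean(counts) / (7.8 * 1.07) - 1), 0.1)
  tmin <- exposure$tmin[match(days, exposure$date)]
  r <- cor(counts, tmin)
  expect_lt(abs(r), 3 / sqrt(length(days)))
})

test_that("true cumulative log OR is the summed lag-weighted contrast", {
  cfg <- sim_config(seed = 1,
                    response = list(a = 0.004, vertex = 69, weights = rep(1, 6)))
  expect_equal(true_cumulative_log_or(cfg, 69, 69), 0)
  expect_equal(true_cumulative_log_or(cfg, 76, 69), 6 * 0.004 * (76 - 69)^2)
  # quadratic truth is minimized at the vertex
  ts <- seq(55, 85, 0.1)
  vals <- vapply(ts, true_cumulative_log_or, numeric(1),
                 config = cfg, reference = 69)
  expect_equal(ts[which.min(vals)], 69)
})

test_that("encounter fields respect the configured mixtures and taxonomy", {
  cfg <- sim_config(seed = 23)
  study <- simulate_study(cfg)
  enc <- study$encounters
  cl <- classify_encounters(enc)
  unsched <- !enc$scheduled
  expect_gt(mean(cl$is_case[unsched]), 0.9)  # only the small non-MH padding
  expect_true(all(enc$sex %in% names(cfg$sex_mix)))
  expect_true(all(enc$race_eth %in% names(cfg$race_mix)))
  mh <- cl[cl$is_case & !enc$scheduled, ]
  expect_lt(abs(mean(mh$suicide_flag) - cfg$suicide_ecode_rate), 0.02)
  # every encounter date has full lag-0..5 exposure coverage
  spec <- crossbasis_spec(spline_spec(3, c(64, 71), c(45, 92)))
  expect_no_error(build_crossbasis(study$exposure,
                                   unique(enc$admit_date), spec))
})

test_that("a written study is readable by the pipeline input parsers", {
  tmp <- withr::local_tempdir()
  cfg <- sim_config(seed = 2, years = 2005)
  study <- simulate_study(cfg)
  write_study(study, tmp, config = cfg)
  expect_true(file.exists(file.path(tmp, "truth.json")))
  stations <- read_station_csv(file.path(tmp, "stations.csv"))
  city <- average_stations(stations)
  expect_equal(city$tmin, study$exposure$tmin, tolerance = 1e-6)
  enc <- read_encounters_csv(file.path(tmp, "encounters.csv"))
  expect_equal(nrow(enc), nrow(study$encounters))
  truth <- jsonlite::read_json(file.path(tmp, "truth.json"))
  expect_equal(truth$response$vertex, cfg$response$vertex)
})
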
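# Shared fixtures and independent oracles for the test suite.

# A gap-free constant-or-specified exposure series.
make_exposure <- function(from = "2005-05-20", to = "2005-08-31",
                          tmin = NULL, tmean_offset = 10, rh = 60) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  if (is.null(tmin)) tmin <- rep(70, length(dates))
  if (length(tmin) == 1) tmin <- rep(tmin, length(dates))
  tmean <- tmin + tmean_offset
  ccdlnm:::new_city_series(dates, tmin, tmean, rep(rh, length(dates)))
}

# Minimal valid encounter line-list rows.
make_encounters <- function(admit_date, age_years = 15, sex = "male",
                            race_eth = "nh_white", payer = "medicaid",
                            primary_dx = "296.20", ecodes = "",
                            setting = "ED", scheduled = FALSE) {
  data.frame(admit_date = as.Date(admit_date), age_years = age_years,
             sex = sex, race_eth = race_eth, payer = payer,
             primary_dx = primary_dx, ecodes = ecodes, setting = setting,
             scheduled = scheduled, stringsAsFactors = FALSE)
}

# Random small matched-set fixture with a softmax-chosen case per stratum.
rand_clogit_fixture <- function(seed) {
  set.seed(seed)
  n_strata <- sample(6:10, 1)
  p <- sample(1:3, 1)
  m <- sample(3:5, n_strata, replace = TRUE)
  X <- matrix(stats::rnorm(sum(m) * p), ncol = p)
  stratum <- rep(seq_len(n_strata), m)
  beta <- stats::rnorm(p, 0, 0.5)
  case <- logical(sum(m))
  for (s in seq_len(n_strata)) {
    idx <- which(stratum == s)
    pr <- exp(drop(X[idx, , drop = FALSE] %*% beta))
    case[idx[sample.int(length(idx), 1, prob = pr)]] <- TRUE
  }
  list(X = X, stratum = stratum, case = case)
}

# Fit a random fixture, discarding separated or near-separated draws (flat
# likelihood ridges where no maximizer is numerically well defined).
fit_usable_fixture <- function(fx, beta_cap = 2.5) {
  fit <- tryCatch(fit_clogit(fx$X, fx$stratum, fx$case),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged || max(abs(fit$beta)) > beta_cap)
    return(NULL)
  fit
}

# Independent maximizer of the conditional likelihood: coordinate-wise grid
# search with bracket shrinkage (no gradients, no Newton steps).
grid_zoom_max <- function(f, p, half_width = 6, pts = 15, sweeps = 45) {
  b <- rep(0, p)
  w <- half_width
  for (it in seq_len(sweeps)) {
    for (j in seq_len(p)) {
      g <- seq(b[j] - w, b[j] + w, length.out = pts)
      vals <- vapply(g, function(v) { bb <- b; bb[j] <- v; f(bb) }, numeric(1))
      b[j] <- g[which.max(vals)]
    }
    w <- w * 0.65
  }
  b
}

# Single-age-group simulation/run configs used by the Monte-Carlo checks:
# one pooled 6-25 group keeps the per-study encounter count near 5,000 while
# fitting one model per study.
mc_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_expected_daily = c("6-25" = 7.8), ...)
}

mc_run_config <- function(...) {
  run_config(age_breaks = 6L, subgroup_vars = character(0), ...)
}

run_overall <- function(study, rcfg = mc_run_config()) {
  run <- run_analysis(study$exposure, study$encounters, rcfg)
  run$results[run$results$variable == "overall", , drop = FALSE]
}
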
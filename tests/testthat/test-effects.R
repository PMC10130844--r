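# Cumulative exposure-response, MRT, ORs and heterogeneity.

# a small converged fit on synthetic strata, reused across tests
make_small_fit <- function(seed = 13, n = 250) {
  set.seed(seed)
  exposure <- make_exposure("2005-05-20", "2005-08-31",
                            tmin = rnorm(104, 68, 5))
  enc <- make_encounters(
    sample(seq(as.Date("2005-06-01"), as.Date("2005-08-31"), by = "day"),
           n, replace = TRUE))
  spl <- spline_spec(3, c(64, 71), c(52, 84))
  spec <- crossbasis_spec(spl)
  st <- build_strata(enc, exposure, spec, collapse = TRUE)
  list(fit = fit_conditional_logistic(st), spec = spec)
}

test_that("curve is zero with zero SE at the reference", {
  f <- make_small_fit()
  cv <- exposure_response_curve(f$fit, f$spec, grid = seq(55, 82, 0.5),
                                reference = 68)
  i <- which(cv$grid == 68)
  expect_equal(cv$cum_log_or[i], 0)
  expect_equal(cv$se[i], 0)
  expect_true(all(cv$se >= 0))
  expect_true(all(cv$se[cv$grid != 68] > 0))
})

test_that("beta = 0 gives a flat zero curve with covariance-only SEs", {
  f <- make_small_fit()
  fit0 <- f$fit
  fit0$beta[] <- 0
  cv <- exposure_response_curve(fit0, f$spec, grid = seq(55, 82, 0.5),
                                reference = 68)
  expect_true(all(cv$cum_log_or == 0))
  expect_true(all(cv$se[cv$grid != 68] > 0))
})

test_that("curve equals the hand linear-algebra contrast on a 2x2 toy", {
  # hand-assembled fit: df = 1 spline (affine), 2 lags, explicit beta, Sigma
  spl <- spline_spec(1, numeric(0), c(50, 85))
  spec <- crossbasis_spec(spl, lag_min = 0, lag_max = 1)
  fit <- structure(list(beta = c(0.02, -0.01),
                        cov = matrix(c(4e-4, 1e-4, 1e-4, 9e-4), 2),
                        loglik = -1, n_strata = 10,
                        n_informative_strata = 10, converged = TRUE,
                        iterations = 3, max_score = 0), class = "cc_fit")
  grid <- c(60, 70, 76)
  cv <- exposure_response_curve(fit, spec, grid, reference = 65)
  for (i in seq_along(grid)) {
    cvec <- rep(grid[i] - 65, 2)  # ns with df=1 is the identity map here
    expect_equal(cv$cum_log_or[i], sum(cvec * fit$beta))
    expect_equal(cv$se[i], sqrt(drop(t(cvec) %*% fit$cov %*% cvec)))
  }
})

test_that("re-referencing shifts the curve by a constant; OR inverts", {
  f <- make_small_fit()
  g <- seq(55, 82, 0.5)
  c1 <- exposure_response_curve(f$fit, f$spec, g, reference = 60)
  c2 <- exposure_response_curve(f$fit, f$spec, g, reference = 75)
  shift <- c1$cum_log_or - c2$cum_log_or
  expect_lt(max(abs(shift - shift[1])), 1e-10)
  or_ab <- cumulative_or(c1, 75)[["or"]]  # 75 vs 60
  or_ba <- cumulative_or(c2, 60)[["or"]]  # 60 vs 75
  expect_equal(or_ab * or_ba, 1, tolerance = 1e-10)
})

test_that("an unconverged fit is rejected", {
  f <- make_small_fit()
  bad <- f$fit
  bad$converged <- FALSE
  expect_error(exposure_response_curve(bad, f$spec, 55:80, 68),
               "converge")
})

test_that("MRT minimizes the curve with ties toward the lowest temperature", {
  # flat curve: beta = 0 -> lowest grid temperature
  f <- make_small_fit()
  fit0 <- f$fit
  fit0$beta[] <- 0
  cv <- find_mrt(fit0, f$spec, range = c(55, 82), step = 0.1)
  expect_equal(attr(cv, "mrt"), 55)

  # strictly increasing cumulative response -> boundary minimum
  spl1 <- spline_spec(1, numeric(0), c(50, 85))
  spec1 <- crossbasis_spec(spl1, 0, 0)
  fit_up <- structure(list(beta = 0.1, cov = matrix(1e-4), loglik = -1,
                           n_strata = 5, n_informative_strata = 5,
                           converged = TRUE, iterations = 2, max_score = 0),
                      class = "cc_fit")
  cv_up <- find_mrt(fit_up, spec1, range = c(55, 82), step = 0.1)
  expect_equal(attr(cv_up, "mrt"), 55)

  # curve referenced at its MRT is zero there and non-negative nearby
  expect_equal(min(cv_up$cum_log_or), 0)
})

test_that("MRT recovers the vertex of a known U-shaped truth", {
  # simulate a study whose true cumulative response is a parabola with
  # vertex 69.2 F (truth constructed, then estimated end to end)
  cfg <- mc_sim_config(seed = 31,
                       n_expected_daily = c("6-25" = 20),
                       response = list(a = 0.004, vertex = 69.2,
                                       weights = c(0.30, 0.25, 0.20, 0.15,
                                                   0.07, 0.03)))
  study <- simulate_study(cfg)
  ov <- run_overall(study)
  expect_equal(ov$status, "ok")
  expect_lt(abs(ov$mrt_f - 69.2), 1.5)
})

test_that("cumulative OR and Wald limits are the hand exponentials", {
  f <- make_small_fit()
  g <- seq(55, 82, 0.5)
  cv <- exposure_response_curve(f$fit, f$spec, g, reference = 65)
  # overwrite with a hand point: log-OR 0.25, se 0.07 at t = 70
  cv$cum_log_or[cv$grid == 70] <- 0.25
  cv$se[cv$grid == 70] <- 0.07
  est <- cumulative_or(cv, 70, level = 0.95)
  expect_equal(unname(est["or"]), 1.2840254166877414)
  expect_equal(unname(est["ci_low"]), 1.1194108510763516, tolerance = 1e-9)
  expect_equal(unname(est["ci_high"]), 1.4728473188506495, tolerance = 1e-9)
  # reference point: OR and CI collapse to 1
  est_ref <- cumulative_or(cv, 65)
  expect_equal(unname(est_ref), c(1, 1, 1))
  # widening the level strictly widens the interval
  est99 <- cumulative_or(cv, 70, level = 0.99)
  expect_lt(est99[["ci_low"]], est[["ci_low"]])
  expect_gt(est99[["ci_high"]], est[["ci_high"]])
  expect_error(cumulative_or(cv, 90), "outside")
})

test_that("Cochran's Q matches hand arithmetic and its scale law", {
  q0 <- cochran_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.05))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)

  # hand evaluation: theta = {0.2, 0}, se = {0.1, 0.1}: w = 100, pooled 0.1,
  # Q = 100*0.01 + 100*0.01 = 2, df 1, p = P(chi2_1 > 2)
  q <- cochran_q(c(0.2, 0), c(0.1, 0.1))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1L)
  expect_equal(q$p, 0.15729920705028105, tolerance = 1e-12)

  # scaling both SEs by 10 shrinks Q by 100
  q10 <- cochran_q(c(0.2, 0), c(1, 1))
  expect_equal(q10$Q, q$Q / 100)

  expect_error(cochran_q(0.2, 0.1), "at least two")
  expect_error(cochran_q(c(0.2, 0), c(0.1, 0)), "must be > 0")
})
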
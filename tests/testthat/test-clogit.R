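# Conditional logistic regression: likelihood and Newton-Raphson fitter.

test_that("conditional log-likelihood at beta = 0 is -sum log(m_i + 1)", {
  fx <- rand_clogit_fixture(1)
  m <- table(fx$stratum) - 1
  expect_equal(
    conditional_loglik(rep(0, ncol(fx$X)), fx$X, fx$stratum, fx$case),
    -sum(log(m + 1)))
})

test_that("stratum-constant shifts leave the likelihood unchanged", {
  fx <- rand_clogit_fixture(2)
  b <- rnorm(ncol(fx$X))
  ll <- conditional_loglik(b, fx$X, fx$stratum, fx$case)
  X2 <- fx$X
  X2[fx$stratum == 1, ] <- X2[fx$stratum == 1, , drop = FALSE] +
    matrix(c(3, -1, 0.5)[seq_len(ncol(X2))], sum(fx$stratum == 1),
           ncol(X2), byrow = TRUE)
  expect_equal(conditional_loglik(b, X2, fx$stratum, fx$case), ll)
})

test_that("single 1:3 stratum hand value: ln 2 - ln 5 at beta = ln 2", {
  X <- matrix(c(1, 0, 0, 0), ncol = 1)
  expect_equal(
    conditional_loglik(log(2), X, rep(1, 4), c(TRUE, FALSE, FALSE, FALSE)),
    log(2 / 5))
})

test_that("paired binary exposure recovers the discordant-pair estimator", {
  # 10 pairs case-exposed-only, 5 pairs referent-exposed-only: beta = ln(10/5)
  X <- matrix(c(rep(c(1, 0), 10), rep(c(0, 1), 5)), ncol = 1)
  stratum <- rep(1:15, each = 2)
  case <- rep(c(TRUE, FALSE), 15)
  fit <- fit_clogit(X, stratum, case)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), log(2), tolerance = 1e-8)
  # classical variance of ln(n10/n01): 1/n10 + 1/n01
  expect_equal(unname(fit$cov[1, 1]), 1 / 10 + 1 / 5, tolerance = 1e-6)
})

test_that("Newton-Raphson matches a brute-force grid maximizer", {
  checked <- 0L
  seed <- 0L
  while (checked < 12L) {
    seed <- seed + 1L
    fx <- rand_clogit_fixture(seed)
    fit <- fit_usable_fixture(fx)
    if (is.null(fit)) next  # separated or near-separated draw
    oracle <- grid_zoom_max(
      function(b) conditional_loglik(b, fx$X, fx$stratum, fx$case),
      p = ncol(fx$X))
    expect_lt(max(abs(fit$beta - oracle)), 1e-4)
    checked <- checked + 1L
  }
  expect_equal(checked, 12L)
})

test_that("estimates agree with an established implementation", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))  # clogit needs coxph attached
  n_checked <- 0L
  for (seed in c(101, 202, 303, 404, 505, 606, 707)) {
    fx <- rand_clogit_fixture(seed)
    fit <- fit_usable_fixture(fx)
    if (is.null(fit)) next
    XX <- fx$X
    colnames(XX) <- paste0("X", seq_len(ncol(XX)))
    df <- data.frame(y = fx$case, XX, sid = fx$stratum)
    fml <- stats::as.formula(paste("y ~",
      paste(colnames(XX), collapse = " + "),
      "+ survival::strata(sid)"))
    ref <- survival::clogit(fml, data = df,
                            control = survival::coxph.control(
                              eps = 1e-11, toler.inf = 1e-7, iter.max = 50))
    expect_lt(max(abs(fit$beta - coef(ref))), 1e-6)
    expect_lt(max(abs(fit$cov - stats::vcov(ref))), 1e-6)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 4L)
})

test_that("within-stratum constant exposure is a non-identifiability error", {
  X <- matrix(rep(c(1, 1, 1, 2, 2, 2), 2), ncol = 1)
  stratum <- rep(1:4, each = 3)
  case <- rep(c(TRUE, FALSE, FALSE), 4)
  expect_error(fit_clogit(X, stratum, case), "no informative strata")
})

test_that("aliased columns and separation are explicit errors", {
  set.seed(5)
  x <- rnorm(12)
  X <- cbind(a = x, b = 2 * x)  # collinear
  stratum <- rep(1:4, each = 3)
  case <- rep(c(TRUE, FALSE, FALSE), 4)
  expect_error(fit_clogit(X, stratum, case), "aliased")

  # case value is the stratum maximum everywhere: separation
  Xs <- matrix(rep(c(2, 1, 0), 4), ncol = 1)
  expect_error(fit_clogit(Xs, stratum, case), "separation")
})

test_that("uninformative strata are counted but excluded from information", {
  set.seed(6)
  X <- matrix(c(rnorm(6), rep(1, 3)), ncol = 1)
  stratum <- rep(1:3, each = 3)
  case <- rep(c(TRUE, FALSE, FALSE), 3)
  fit <- fit_clogit(X, stratum, case)
  expect_equal(fit$n_strata, 3)
  expect_equal(fit$n_informative_strata, 2)
  # observed information positive definite on identifiable fixtures
  expect_true(all(eigen(solve(fit$cov), symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("per-stratum weights reproduce replicated strata", {
  fx <- rand_clogit_fixture(7)
  # duplicate stratum 1 three times explicitly
  i1 <- which(fx$stratum == 1)
  Xd <- rbind(fx$X, fx$X[rep(i1, 2), , drop = FALSE])
  sd_ <- c(fx$stratum, rep(max(fx$stratum) + 1:2, each = length(i1)))
  cd <- c(fx$case, rep(fx$case[i1], 2))
  w <- rep(1, max(fx$stratum)); w[1] <- 3
  f1 <- tryCatch(fit_clogit(Xd, sd_, cd), error = function(e) NULL)
  f2 <- tryCatch(fit_clogit(fx$X, fx$stratum, fx$case, weights = w),
                 error = function(e) NULL)
  skip_if(is.null(f1) || is.null(f2), "fixture separated")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})
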
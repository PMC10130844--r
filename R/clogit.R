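# Conditional logistic regression on matched sets by direct maximization of
# the conditional likelihood (exact for 1:m matching).

# Internal: normalize stratum labels to contiguous integers and a split index.
stratum_index <- function(stratum) {
  sid <- match(stratum, unique(stratum))
  list(sid = sid, n = max(sid), split = split(seq_along(sid), sid))
}

#' Conditional log-likelihood of a matched-set logistic model
#'
#' For matched set i with case row x_case and member rows x_j (case plus
#' referents), the contribution is x_case' beta - log sum_j exp(x_j' beta),
#' stabilized by subtracting the per-stratum maximum before exponentiation.
#' Optional per-stratum weights multiply contributions (used to collapse
#' identical matched sets).
#'
#' @param beta Coefficient vector.
#' @param X Design matrix (rows = stratum members).
#' @param stratum Stratum identifier per row.
#' @param case Logical per row; exactly one TRUE per stratum.
#' @param weights Optional per-stratum weights (aligned to the strata in
#'   first-appearance order), default 1.
#' @return The log-likelihood (scalar, <= 0 for unit weights).
#' @export
conditional_loglik <- function(beta, X, stratum, case, weights = NULL) {
  if (length(beta) != ncol(X)) stop("dimension mismatch: beta vs design columns")
  ix <- stratum_index(stratum)
  if (!all(vapply(ix$split, function(r) sum(case[r]) == 1L, logical(1))))
    stop("each stratum must contain exactly one case row")
  if (is.null(weights)) weights <- rep(1, ix$n)
  eta <- drop(X %*% beta)
  mx <- vapply(ix$split, function(r) max(eta[r]), numeric(1))
  lse <- mx + log(drop(rowsum(exp(eta - mx[ix$sid]), ix$sid, reorder = TRUE)))
  sum(weights * (eta[case][order(ix$sid[case])] - lse))
}

#' Fit a conditional logistic regression
#'
#' Newton-Raphson with analytic gradient and Hessian and step-halving on
#' likelihood decrease, starting from beta = 0.  Convergence when the maximum
#' absolute score falls below `tol_score` or the relative log-likelihood
#' change falls below `tol_loglik` (default 1e-8 / 1e-12, at most `max_iter`
#' iterations).  The covariance is the inverse observed information at the
#' optimum.  Uninformative strata (all member rows identical) contribute a
#' constant to the likelihood and nothing to the score or information; they
#' are counted but cannot drive the fit.  A design that is rank-deficient on
#' the informative strata, or a column that perfectly ranks cases above (or
#' below) referents in every informative stratum (separation), is reported as
#' an explicit error naming the columns.
#'
#' @inheritParams conditional_loglik
#' @param max_iter,tol_score,tol_loglik Newton-Raphson controls.
#' @return A `cc_fit` list: `beta`, `cov`, `loglik`, `n_strata`,
#'   `n_informative_strata` (weighted counts), `converged`, `iterations`,
#'   `max_score`.
#' @export
fit_clogit <- function(X, stratum, case, weights = NULL,
                       max_iter = 50L, tol_score = 1e-8, tol_loglik = 1e-12) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  ix <- stratum_index(stratum)
  sid <- ix$sid
  if (!all(vapply(ix$split, function(r) sum(case[r]) == 1L, logical(1))))
    stop("each stratum must contain exactly one case row")
  if (is.null(weights)) weights <- rep(1, ix$n)
  stopifnot(length(weights) == ix$n, all(weights > 0))

  n_per <- as.numeric(tabulate(sid, ix$n))
  if (any(n_per < 2L)) stop("every stratum needs at least one referent")

  # informative strata: some column varies within the stratum
  s1 <- rowsum(X, sid, reorder = TRUE)
  s2 <- rowsum(X^2, sid, reorder = TRUE)
  wv <- s2 - s1^2 / n_per
  informative <- rowSums(abs(wv) > 1e-10 * pmax(s2, 1)) > 0
  if (!any(informative))
    stop("no informative strata: exposure is constant within every matched set")

  inf_rows <- informative[sid]
  Xc <- X - (s1 / n_per)[sid, , drop = FALSE]   # within-stratum centered
  qrk <- qr(Xc[inf_rows, , drop = FALSE])
  if (qrk$rank < p) {
    dropped <- colnames(X)[qrk$pivot[(qrk$rank + 1L):p]]
    stop("design not identifiable on informative strata; aliased column(s): ",
         paste(dropped, collapse = ", "))
  }

  # separation check: a column whose case value is an extreme of its stratum
  # in every informative stratum (strictly so in at least one)
  ord <- order(sid[case])
  case_rows <- which(case)[ord]
  mx <- apply(X, 2, function(col) vapply(ix$split, function(r) max(col[r]),
                                         numeric(1)))
  mn <- apply(X, 2, function(col) vapply(ix$split, function(r) min(col[r]),
                                         numeric(1)))
  xc <- X[case_rows, , drop = FALSE]
  sep <- vapply(seq_len(p), function(j) {
    i <- informative & (mx[, j] > mn[, j])
    if (!any(i)) return(FALSE)
    all(xc[i, j] >= mx[i, j] - 1e-12) || all(xc[i, j] <= mn[i, j] + 1e-12)
  }, logical(1))
  if (any(sep))
    stop("separation: column(s) ", paste(colnames(X)[sep], collapse = ", "),
         " perfectly rank cases against referents")

  w_case <- weights  # aligned to strata order
  beta <- numeric(p)
  ll <- conditional_loglik(beta, X, sid, case, weights)
  converged <- FALSE
  iter <- 0L
  max_score <- Inf
  H <- NULL
  repeat {
    eta <- drop(X %*% beta)
    emax <- vapply(ix$split, function(r) max(eta[r]), numeric(1))
    ee <- exp(eta - emax[sid])
    denom <- drop(rowsum(ee, sid, reorder = TRUE))
    pr <- ee / denom[sid]
    wpr <- weights[sid] * pr
    M <- rowsum(pr * X, sid, reorder = TRUE)            # per-stratum E[x]
    grad <- colSums(w_case * X[case_rows, , drop = FALSE]) -
      drop(crossprod(X, wpr))
    H <- crossprod(X, wpr * X) - crossprod(sqrt(weights) * M)
    max_score <- max(abs(grad))
    if (max_score < tol_score) { converged <- TRUE; break }
    if (iter >= max_iter) break
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("observed information is singular; model not identifiable"))
    new_beta <- beta + step
    new_ll <- conditional_loglik(new_beta, X, sid, case, weights)
    h <- 0L
    while (!is.finite(new_ll) || new_ll < ll - 1e-12) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- conditional_loglik(new_beta, X, sid, case, weights)
      h <- h + 1L
      if (h > 40L) break
    }
    iter <- iter + 1L
    rel <- abs(new_ll - ll) / (abs(ll) + 1e-10)
    beta <- new_beta
    ll <- new_ll
    if (rel < tol_loglik) {
      eta <- drop(X %*% beta)
      emax <- vapply(ix$split, function(r) max(eta[r]), numeric(1))
      ee <- exp(eta - emax[sid])
      pr <- ee / drop(rowsum(ee, sid, reorder = TRUE))[sid]
      wpr <- weights[sid] * pr
      M <- rowsum(pr * X, sid, reorder = TRUE)
      grad <- colSums(w_case * X[case_rows, , drop = FALSE]) -
        drop(crossprod(X, wpr))
      H <- crossprod(X, wpr * X) - crossprod(sqrt(weights) * M)
      max_score <- max(abs(grad))
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(beta)) > 30)
    warning("possible separation: coefficients diverging without convergence")
  cov <- tryCatch(solve(H), error = function(e)
    stop("observed information is singular at the optimum"))
  cov <- (cov + t(cov)) / 2
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, cov = cov, loglik = ll,
                 n_strata = sum(weights),
                 n_informative_strata = sum(weights[informative]),
                 converged = converged, iterations = iter,
                 max_score = max_score),
            class = "cc_fit")
}

#' Fit the DLNM conditional logistic model on assembled strata
#'
#' High-level wrapper around [fit_clogit()] taking a `cc_strata` object;
#' optionally appends extra covariate columns (e.g. lag-0 relative humidity
#' for the humidity-adjusted sensitivity model).
#'
#' @param strata A `cc_strata` from [build_strata()].
#' @param extra Optional numeric matrix/vector of extra covariates aligned to
#'   `strata$rows`.
#' @param ... Passed to [fit_clogit()].
#' @return A `cc_fit` with attributes `n_cb_cols` (number of cross-basis
#'   columns) and `spec`.
#' @export
fit_conditional_logistic <- function(strata, extra = NULL, ...) {
  stopifnot(inherits(strata, "cc_strata"))
  X <- strata$X
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (nrow(extra) != nrow(X)) stop("extra covariates not aligned to rows")
    if (is.null(colnames(extra)))
      colnames(extra) <- paste0("z", seq_len(ncol(extra)))
    X <- cbind(X, extra)
  }
  fit <- fit_clogit(X, strata$rows$stratum_id, strata$rows$is_case,
                    weights = strata$strata$weight, ...)
  attr(fit, "n_cb_cols") <- ncol(strata$X)
  attr(fit, "spec") <- strata$spec
  fit
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("Conditional logistic fit:", length(x$beta), "coefficients,",
      x$n_strata, "matched sets (", x$n_informative_strata, "informative )\n")
  cat("  log-likelihood:", format(x$loglik), " converged:", x$converged,
      "in", x$iterations, "iterations\n")
  invisible(x)
}
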
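# End-to-end orchestration: cohort -> strata -> DLNM fit -> MRT-referenced
# cumulative ORs -> subgroups -> heterogeneity, plus sensitivity variants.

#' Analysis run configuration
#'
#' @param years,months Analysis years and calendar months (defaults
#'   2005-2011, June-August).
#' @param age_range,age_breaks Cohort age bounds and group cut points.
#' @param spline_df Exposure spline degrees of freedom (default 3; 5 is the
#'   usual alternative).
#' @param lag_max Maximum lag in days (default 5).
#' @param percentile Elevated-temperature percentile of the warm-season
#'   exposure distribution (default 0.95).
#' @param min_subgroup Minimum encounters for a subgroup analysis
#'   (default 500).
#' @param subgroup_vars Stratification variables; any of `sex`, `race_eth`,
#'   `payer`, `subcategory`, `suicide`.
#' @param subgroup_reference `"own"` (each subgroup referenced at its own
#'   MRT, the default) or `"shared"` (the age group's MRT).
#' @param mrt_step MRT search resolution in degrees F (default 0.1).
#' @param rh_adjust Add lag-0 relative humidity as a linear covariate.
#' @param months_restrict Optional subset of `months` to restrict cases to
#'   (e.g. `7:8` for the July-August sensitivity model).
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return A `run_config` list.
#' @export
run_config <- function(years = 2005:2011, months = 6:8,
                       age_range = c(6L, 25L), age_breaks = c(6L, 12L, 18L),
                       spline_df = 3L, lag_max = 5L, percentile = 0.95,
                       min_subgroup = 500L,
                       subgroup_vars = c("sex", "race_eth", "payer",
                                         "subcategory", "suicide"),
                       subgroup_reference = c("own", "shared"),
                       mrt_step = 0.1, rh_adjust = FALSE,
                       months_restrict = NULL, conf_level = 0.95) {
  stopifnot(all(months %in% 6:8), percentile > 0, percentile < 1)
  if (!is.null(months_restrict)) stopifnot(all(months_restrict %in% months))
  structure(list(years = years, months = months, age_range = age_range,
                 age_breaks = age_breaks, spline_df = as.integer(spline_df),
                 lag_max = as.integer(lag_max), percentile = percentile,
                 min_subgroup = as.integer(min_subgroup),
                 subgroup_vars = subgroup_vars,
                 subgroup_reference = match.arg(subgroup_reference),
                 mrt_step = mrt_step, rh_adjust = isTRUE(rh_adjust),
                 months_restrict = months_restrict, conf_level = conf_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# one analysis (fit + MRT + OR at elevated temperature) on a set of
# encounters sharing a spline spec
analyze_subset <- function(encounters, exposure, cbspec, p95, obs_range,
                           config) {
  strata <- build_strata(encounters, exposure, cbspec, collapse = TRUE)
  extra <- NULL
  if (config$rh_adjust) {
    rh <- exposure$rh[as.integer(strata$rows$date) -
                        as.integer(exposure$date[1]) + 1L]
    if (anyNA(rh)) stop("relative humidity missing on an analysis day")
    extra <- matrix(rh, ncol = 1, dimnames = list(NULL, "rh_lag0"))
  }
  fit <- fit_conditional_logistic(strata, extra = extra)
  curve <- find_mrt(fit, cbspec, range = obs_range, step = config$mrt_step)
  mrt <- attr(curve, "mrt")
  est <- cumulative_or(curve, p95, level = config$conf_level)
  lo <- stats::approx(curve$grid, curve$cum_log_or, xout = p95)$y
  se <- stats::approx(curve$grid, curve$se, xout = p95)$y
  list(fit = fit, curve = curve, mrt = mrt, or = est, log_or = lo, se = se,
       n_dropped_gap = strata$n_dropped_gap)
}

#' Run the full case-crossover DLNM analysis
#'
#' Per age group: assemble time-stratified strata, fit the conditional
#' logistic DLNM, locate the minimum-risk temperature over the observed
#' warm-season range, compute the cumulative OR at the elevated-temperature
#' percentile, repeat for each subgroup level with at least
#' `config$min_subgroup` encounters (unknown levels excluded from their
#' stratified analysis), and test subgroup homogeneity with Cochran's Q.
#' Interior spline knots are placed once per age group from the analysis
#' sample (case and referent exposure days) and shared by that group's
#' subgroup fits so estimates are comparable.
#'
#' @param exposure A `city_series`.
#' @param encounters Raw line-list data frame (or CSV path).
#' @param config A `run_config`.
#' @param tax A `dx_taxonomy`.
#' @param variant Label recorded on the results (default `"main"`).
#' @return A `cc_run` bundle: `results` data frame (one row per
#'   age_group x variable x level with n, MRT, elevated temperature, OR, CI
#'   and status), `heterogeneity` (Cochran's Q per variable), `curves`
#'   (per age group `erc`), `attrition`, `manifest`.
#' @export
run_analysis <- function(exposure, encounters, config = run_config(),
                         tax = default_taxonomy(), variant = "main") {
  if (is.character(encounters)) encounters <- read_encounters_csv(encounters)
  filtered <- apply_cohort_filters(encounters, tax, years = config$years,
                                   months = config$months,
                                   age_range = config$age_range,
                                   age_breaks = config$age_breaks)
  attrition <- attr(filtered, "attrition")
  if (!is.null(config$months_restrict)) {
    mo <- as.POSIXlt(filtered$admit_date)$mon + 1L
    filtered <- filtered[mo %in% config$months_restrict, , drop = FALSE]
  }
  p95 <- as.numeric(exposure_percentile(exposure, config$percentile,
                                        months = config$months))
  results <- list(); hetero <- list(); curves <- list(); manifest_groups <- list()
  groups <- sort(unique(filtered$age_group))
  for (g in groups) {
    sub_g <- filtered[filtered$age_group == g, , drop = FALSE]
    # analysis-sample exposure days (cases + referents), for knot placement
    udates <- sort(unique(sub_g$admit_date))
    samp_dates <- unique(c(udates, as.Date(unlist(lapply(udates,
                    select_referents), use.names = FALSE),
                    origin = "1970-01-01")))
    tidx <- as.integer(samp_dates) - as.integer(exposure$date[1]) + 1L
    tidx[tidx < 1L | tidx > nrow(exposure)] <- NA_integer_
    tv <- exposure$tmin[tidx]
    tv <- tv[!is.na(tv)]
    spl <- spline_spec_from_sample(tv, df = config$spline_df)
    cbspec <- crossbasis_spec(spl, lag_min = 0L, lag_max = config$lag_max)
    obs_range <- range(tv)
    res_g <- tryCatch(analyze_subset(sub_g, exposure, cbspec, p95, obs_range,
                                     config),
                      error = function(e) e)
    if (inherits(res_g, "error")) {
      results[[length(results) + 1L]] <- data.frame(
        variant = variant, age_group = g, variable = "overall",
        level = "overall", n = nrow(sub_g), mrt_f = NA, elevated_f = p95,
        or = NA, ci_low = NA, ci_high = NA, log_or = NA, se = NA,
        status = paste0("fit_failed: ", conditionMessage(res_g)))
      next
    }
    curves[[g]] <- res_g$curve
    manifest_groups[[g]] <- list(
      interior_knots = spl$interior_knots, boundary_knots = spl$boundary_knots,
      n_strata = res_g$fit$n_strata,
      n_informative = res_g$fit$n_informative_strata,
      n_dropped_gap = res_g$n_dropped_gap,
      converged = res_g$fit$converged, iterations = res_g$fit$iterations)
    results[[length(results) + 1L]] <- data.frame(
      variant = variant, age_group = g, variable = "overall",
      level = "overall", n = nrow(sub_g), mrt_f = res_g$mrt,
      elevated_f = p95, or = res_g$or[["or"]], ci_low = res_g$or[["ci_low"]],
      ci_high = res_g$or[["ci_high"]], log_or = res_g$log_or, se = res_g$se,
      status = "ok")
    shared_mrt <- res_g$mrt
    for (v in config$subgroup_vars) {
      if (v == "suicide") {
        levels_v <- "suicide_self_harm"
      } else {
        levels_v <- sort(unique(sub_g[[v]]))
        levels_v <- setdiff(levels_v, c("unknown", NA))
      }
      v_rows <- list()
      for (lev in levels_v) {
        sub_v <- if (v == "suicide") sub_g[sub_g$suicide_flag, , drop = FALSE]
                 else sub_g[sub_g[[v]] == lev, , drop = FALSE]
        n_lev <- nrow(sub_v)
        if (n_lev < config$min_subgroup) {
          v_rows[[lev]] <- data.frame(
            variant = variant, age_group = g, variable = v, level = lev,
            n = n_lev, mrt_f = NA, elevated_f = p95, or = NA, ci_low = NA,
            ci_high = NA, log_or = NA, se = NA,
            status = sprintf("skipped: n<%d", config$min_subgroup))
          next
        }
        res_v <- tryCatch(analyze_subset(sub_v, exposure, cbspec, p95,
                                         obs_range, config),
                          error = function(e) e)
        if (inherits(res_v, "error")) {
          v_rows[[lev]] <- data.frame(
            variant = variant, age_group = g, variable = v, level = lev,
            n = n_lev, mrt_f = NA, elevated_f = p95, or = NA, ci_low = NA,
            ci_high = NA, log_or = NA, se = NA,
            status = paste0("fit_failed: ", conditionMessage(res_v)))
          next
        }
        if (config$subgroup_reference == "shared") {
          curve_s <- exposure_response_curve(res_v$fit, cbspec,
                                             grid = res_v$curve$grid,
                                             reference = shared_mrt)
          est <- cumulative_or(curve_s, p95, level = config$conf_level)
          lo <- stats::approx(curve_s$grid, curve_s$cum_log_or, xout = p95)$y
          se <- stats::approx(curve_s$grid, curve_s$se, xout = p95)$y
          mrt_rep <- shared_mrt
        } else {
          est <- res_v$or; lo <- res_v$log_or; se <- res_v$se
          mrt_rep <- res_v$mrt
        }
        v_rows[[lev]] <- data.frame(
          variant = variant, age_group = g, variable = v, level = lev,
          n = n_lev, mrt_f = mrt_rep, elevated_f = p95, or = est[["or"]],
          ci_low = est[["ci_low"]], ci_high = est[["ci_high"]],
          log_or = lo, se = se, status = "ok")
      }
      v_df <- do.call(rbind, v_rows)
      results[[length(results) + 1L]] <- v_df
      okv <- v_df[v_df$status == "ok" & is.finite(v_df$se) & v_df$se > 0, ,
                  drop = FALSE]
      if (nrow(okv) >= 2L) {
        q <- cochran_q(okv$log_or, okv$se)
        hetero[[length(hetero) + 1L]] <- data.frame(
          variant = variant, age_group = g, variable = v, k = nrow(okv),
          Q = q$Q, df = q$df, p = q$p)
      }
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  hetero <- if (length(hetero)) do.call(rbind, hetero) else
    data.frame(variant = character(), age_group = character(),
               variable = character(), k = integer(), Q = numeric(),
               df = integer(), p = numeric())
  manifest <- list(variant = variant, config = unclass(config),
                   quantile_rule = "type7_linear_order_statistic_interpolation",
                   elevated_f = p95, groups = manifest_groups,
                   package_version = as.character(utils::packageVersion("ccdlnm")))
  structure(list(results = results, heterogeneity = hetero, curves = curves,
                 attrition = attrition, manifest = manifest),
            class = "cc_run")
}

#' Sensitivity analyses
#'
#' Re-runs the analysis with (a) lag-0 relative humidity added as a linear
#' covariate to every design row (`rh_adjust`), and/or (b) cases restricted
#' to a subset of months (`months_restrict`, e.g. July-August).  Output has
#' the same schema as [run_analysis()] with a variant tag.
#'
#' @inheritParams run_analysis
#' @param rh_adjust,months_restrict Sensitivity toggles; defaults taken from
#'   `config`.
#' @export
run_sensitivity <- function(exposure, encounters, config = run_config(),
                            tax = default_taxonomy(),
                            rh_adjust = config$rh_adjust,
                            months_restrict = config$months_restrict) {
  config$rh_adjust <- isTRUE(rh_adjust)
  config$months_restrict <- months_restrict
  tag <- paste0("sensitivity",
                if (config$rh_adjust) "_rh",
                if (!is.null(months_restrict))
                  paste0("_months", paste(months_restrict, collapse = "")))
  run_analysis(exposure, encounters, config, tax, variant = tag)
}

#' Write a run bundle to disk
#'
#' Writes `results.csv`, `heterogeneity.csv`, `curves/<age_group>.csv`
#' (grid, cumulative log OR, SE — enough to replot the exposure-response
#' figure), `manifest.json` (config, knots, convergence: sufficient to
#' recreate the exact basis) and `attrition.log`.
#'
#' @param run A `cc_run`.
#' @param dir Output directory.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "cc_run"))
  dir.create(file.path(dir, "curves"), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$results, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(run$heterogeneity, file.path(dir, "heterogeneity.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  for (g in names(run$curves)) {
    cv <- run$curves[[g]]
    utils::write.csv(data.frame(tmin_f = cv$grid, cum_log_or = cv$cum_log_or,
                                se = cv$se),
                     file.path(dir, "curves", paste0(g, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(paste0(names(run$attrition), ": ", run$attrition),
             file.path(dir, "attrition.log"))
  invisible(dir)
}

#' @export
print.cc_run <- function(x, ...) {
  ov <- x$results[x$results$variable == "overall", , drop = FALSE]
  cat("Case-crossover DLNM run (", x$manifest$variant, "), elevated T = ",
      round(x$manifest$elevated_f, 1), "F\n", sep = "")
  print(ov[c("age_group", "n", "mrt_f", "or", "ci_low", "ci_high", "status")],
        row.names = FALSE)
  invisible(x)
}
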
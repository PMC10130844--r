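# Time-stratified case-crossover referent selection and stratum assembly.

#' Time-stratified referent days for a case day
#'
#' All other dates in the same calendar month and year falling on the same
#' day of the week as the case day, in ascending order.  Every calendar date
#' has 3 or 4 such referents (a weekday occurs 4 or 5 times per month).
#'
#' @param case_date A single `Date` (or coercible).
#' @return Ascending `Date` vector excluding the case day itself.
#' @export
select_referents <- function(case_date) {
  d <- as.Date(case_date)
  stopifnot(length(d) == 1L, !is.na(d))
  lt <- as.POSIXlt(d)
  y <- lt$year + 1900L
  mlen <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[lt$mon + 1L]
  if (lt$mon == 1L && (y %% 4L == 0L && (y %% 100L != 0L || y %% 400L == 0L)))
    mlen <- 29L
  first <- d - (lt$mday - 1L)
  last <- first + (mlen - 1L)
  cand <- seq(d - 28L, d + 28L, by = 7L)  # every same-weekday day of the month
  cand[cand >= first & cand <= last & cand != d]
}

#' Assemble case-crossover strata with cross-basis rows
#'
#' Builds one matched set per encounter (or per distinct case day when
#' `collapse = TRUE`, with a count weight — the conditional likelihood is
#' identical because all matched sets sharing a case day have identical
#' design rows).  Each stratum holds the case day plus its time-stratified
#' referents, with cross-basis rows from the exposure series.  Strata whose
#' lag window touches an exposure gap (a day inside coverage with missing
#' minimum temperature) are dropped and counted; a lag window extending
#' before the start of the exposure series is a coverage error.  Strata
#' whose rows are all identical are retained but flagged uninformative.
#'
#' @param encounters Filtered encounter data frame (needs `admit_date`).
#' @param exposure A `city_series` covering every case/referent date minus
#'   `spec$lag_max` days.
#' @param spec A `crossbasis_spec`.
#' @param collapse Collapse encounters sharing a case day into one weighted
#'   stratum (default FALSE: one stratum per encounter).
#' @return A `cc_strata` object: list with `strata` (stratum_id, case_date,
#'   weight, n_referents, uninformative), `rows` (stratum_id, date, is_case),
#'   `X` (cross-basis matrix aligned to `rows`), `spec`, `n_dropped_gap` and
#'   `dropped_dates`.
#' @export
build_strata <- function(encounters, exposure, spec, collapse = FALSE) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  case_dates <- as.Date(encounters$admit_date)
  if (length(case_dates) == 0) stop("no encounters to build strata from")

  udates <- sort(unique(case_dates))
  refs <- lapply(udates, select_referents)
  all_dates <- unique(c(udates, as.Date(unlist(refs, use.names = FALSE),
                                        origin = "1970-01-01")))
  earliest_needed <- min(all_dates) - spec$lag_max
  if (earliest_needed < min(exposure$date))
    stop("exposure coverage shortfall: series must start on or before ",
         earliest_needed)

  # usable case days: every (case + referent) x lag cell inside coverage and
  # non-missing.  The series is contiguous, so a day is servable iff the
  # lag_min..lag_max window ending on it is fully observed.
  day0 <- as.integer(exposure$date[1])
  nd <- nrow(exposure)
  nlag <- spec$lag_max - spec$lag_min + 1L
  obs <- !is.na(exposure$tmin)
  win <- as.numeric(stats::filter(obs, rep(1, nlag), sides = 1))
  day_ok <- function(d) {
    pos <- as.integer(d) - spec$lag_min - day0 + 1L
    ok <- pos >= nlag & pos <= nd
    ok[ok] <- win[pos[ok]] == nlag
    ok
  }
  usable <- vapply(seq_along(udates), function(i)
    all(day_ok(c(udates[i], refs[[i]]))), logical(1))
  dropped_dates <- udates[!usable]
  n_dropped <- sum(case_dates %in% dropped_dates)
  keep <- !(case_dates %in% dropped_dates)
  case_dates <- case_dates[keep]
  if (length(case_dates) == 0) stop("no strata remain after gap exclusions")

  if (collapse) {
    tab <- table(case_dates)
    set_dates <- as.Date(names(tab))
    weights <- as.numeric(tab)
  } else {
    set_dates <- case_dates
    weights <- rep(1, length(case_dates))
  }
  ref_of <- refs[match(set_dates, udates)]
  n_ref <- lengths(ref_of)

  sid <- rep(seq_along(set_dates), times = n_ref + 1L)
  row_dates <- as.Date(unlist(mapply(function(d, r) c(d, r), set_dates, ref_of,
                                     SIMPLIFY = FALSE), use.names = FALSE),
                       origin = "1970-01-01")
  is_case <- unlist(lapply(n_ref, function(m) c(TRUE, rep(FALSE, m))),
                    use.names = FALSE)

  # compute the cross-basis once on unique dates, then index
  ud_all <- unique(row_dates)
  Xu <- build_crossbasis(exposure, ud_all, spec)
  X <- Xu[match(row_dates, ud_all), , drop = FALSE]

  rng <- rowsum(X, sid, reorder = TRUE)
  sq <- rowsum(X^2, sid, reorder = TRUE)
  n_per <- as.numeric(n_ref + 1L)
  within_var <- sq - rng^2 / n_per
  uninformative <- rowSums(abs(within_var) > 1e-9 * pmax(sq, 1)) == 0

  structure(list(
    strata = data.frame(stratum_id = seq_along(set_dates),
                        case_date = set_dates, weight = weights,
                        n_referents = n_ref, uninformative = uninformative),
    rows = data.frame(stratum_id = sid, date = row_dates, is_case = is_case),
    X = X, spec = spec,
    n_dropped_gap = n_dropped, dropped_dates = dropped_dates
  ), class = "cc_strata")
}

#' Serialize strata to CSV for audit
#'
#' One row per stratum-date: stratum id, date, case indicator, then the
#' cross-basis columns.
#' @param strata A `cc_strata`.
#' @param path Output CSV path.
#' @export
write_strata_csv <- function(strata, path) {
  df <- cbind(data.frame(stratum_id = strata$rows$stratum_id,
                         date = as.character(strata$rows$date),
                         is_case = as.integer(strata$rows$is_case)),
              as.data.frame(strata$X))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
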
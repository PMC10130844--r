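# Encounter line-list parsing, cohort filters and outcome classification.

icd9_dx_pattern    <- "^[0-9]{3}(\\.[0-9]{1,2})?$"
icd9_ecode_pattern <- "^E[0-9]{3}(\\.[0-9])?$"

#' Default mental-health diagnosis taxonomy
#'
#' An approximate, fully overrideable grouping of ICD-9 primary diagnoses
#' into mental-health subcategories, keyed by code prefixes with explicit
#' first-match-wins ordering.  The default case definition is a primary
#' diagnosis with a 3-digit root in 290-299; categories whose conventional
#' ICD-9 roots lie outside that range (anxiety 300, reaction 308/309,
#' personality 301, sexuality 302, eating/elimination/motor 307, externalizing
#' 312/313, ADHD 314, developmental 315) are carried in the map so that they
#' become active if `mh_root_range` is widened in a custom taxonomy.
#' Self-inflicted injury/suicide is flagged separately from any external-cause
#' code starting with `E95`.
#'
#' @return A `dx_taxonomy` list with fields `mh_root_range`, `subcategories`
#'   (ordered named list of character prefix vectors) and
#'   `suicide_ecode_prefix`.
#' @export
default_taxonomy <- function() {
  tax <- list(
    mh_root_range = c(290L, 299L),
    subcategories = list(
      bipolar       = c("296.0", "296.1", "296.4", "296.5", "296.6", "296.7",
                        "296.8"),
      depression    = c("296.2", "296.3", "298.0", "311"),
      psychosis     = c("295", "297", "298"),
      substance_use = c("291", "292", "303", "304", "305"),
      organic       = c("290", "293", "294"),
      autism        = c("299.0"),
      developmental = c("299", "315"),
      anxiety       = c("300.0", "300.2", "300.3", "300"),
      personality   = c("301"),
      sexuality     = c("302"),
      eating        = c("307.1", "307.5"),
      elimination   = c("307.6", "307.7"),
      motor         = c("307.2", "307.3"),
      reaction      = c("308", "309"),
      attachment    = c("313.89"),
      externalizing = c("312", "313"),
      adhd          = c("314")
    ),
    suicide_ecode_prefix = "E95"
  )
  class(tax) <- "dx_taxonomy"
  tax
}

#' Read / write a taxonomy as YAML
#' @param path YAML file path.
#' @export
read_taxonomy_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tax <- default_taxonomy()
  if (!is.null(y$mh_root_range)) tax$mh_root_range <- as.integer(y$mh_root_range)
  if (!is.null(y$subcategories))
    tax$subcategories <- lapply(y$subcategories, as.character)
  if (!is.null(y$suicide_ecode_prefix))
    tax$suicide_ecode_prefix <- y$suicide_ecode_prefix
  tax
}

#' @rdname read_taxonomy_yaml
#' @param tax A `dx_taxonomy`.
#' @export
write_taxonomy_yaml <- function(tax, path) {
  yaml::write_yaml(list(mh_root_range = tax$mh_root_range,
                        subcategories = tax$subcategories,
                        suicide_ecode_prefix = tax$suicide_ecode_prefix), path)
}

#' Read an encounter line-list CSV
#'
#' Expects columns `admit_date,age_years,sex,race_eth,payer,primary_dx,
#' ecodes,setting,scheduled`; `ecodes` is a semicolon-separated list of ICD-9
#' external-cause codes (may be empty).
#'
#' @param path CSV path.
#' @return A data frame with typed columns.
#' @export
read_encounters_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("admit_date", "age_years", "sex", "race_eth", "payer",
            "primary_dx", "ecodes", "setting", "scheduled")
  if (!all(need %in% names(raw)))
    stop("encounter CSV must have columns: ", paste(need, collapse = ", "))
  data.frame(admit_date = as.Date(raw$admit_date),
             age_years = as.integer(raw$age_years),
             sex = raw$sex, race_eth = raw$race_eth, payer = raw$payer,
             primary_dx = raw$primary_dx, ecodes = raw$ecodes,
             setting = raw$setting,
             scheduled = tolower(raw$scheduled) %in% c("true", "t", "1", "yes"),
             stringsAsFactors = FALSE)
}

#' Write an encounter line list to CSV
#' @param encounters Data frame in the line-list schema.
#' @param path Output path.
#' @export
write_encounters_csv <- function(encounters, path) {
  df <- encounters[c("admit_date", "age_years", "sex", "race_eth", "payer",
                     "primary_dx", "ecodes", "setting", "scheduled")]
  df$admit_date <- as.character(df$admit_date)
  df$scheduled <- tolower(as.character(df$scheduled))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

dx_root <- function(code) as.integer(substr(code, 1L, 3L))

#' Classify encounters as mental-health cases
#'
#' An encounter is a case if and only if the 3-digit root of its *primary*
#' diagnosis falls in the taxonomy's mental-health root range; secondary
#' mental-health codes never qualify.  Cases are assigned the first
#' subcategory whose prefix matches the primary code (in the taxonomy's
#' declared order), else `"other_mh"`.  The suicide/self-harm flag is set
#' whenever any external-cause code starts with the suicide prefix; it is an
#' orthogonal marker reported for cases.
#'
#' @param encounters Line-list data frame.
#' @param tax A `dx_taxonomy` (default [default_taxonomy()]).
#' @return `encounters` with added logical `is_case`, character
#'   `subcategory` (NA for non-cases) and logical `suicide_flag`.
#' @export
classify_encounters <- function(encounters, tax = default_taxonomy()) {
  dx <- encounters$primary_dx
  bad <- !grepl(icd9_dx_pattern, dx)
  if (any(bad))
    stop("malformed ICD-9 primary diagnosis code '", dx[bad][1],
         "' in record ", which(bad)[1])
  ec <- encounters$ecodes
  ec[is.na(ec)] <- ""
  ec_items <- strsplit(ec, ";", fixed = TRUE)
  bad_ec <- vapply(ec_items, function(v) {
    v <- trimws(v); v <- v[nzchar(v)]
    any(!grepl(icd9_ecode_pattern, v))
  }, logical(1))
  if (any(bad_ec))
    stop("malformed ICD-9 E-code in record ", which(bad_ec)[1],
         " ('", ec[bad_ec][1], "')")

  root <- dx_root(dx)
  is_case <- root >= tax$mh_root_range[1] & root <= tax$mh_root_range[2]

  sub <- rep(NA_character_, length(dx))
  unassigned <- is_case
  for (cat in names(tax$subcategories)) {
    for (pref in tax$subcategories[[cat]]) {
      hit <- unassigned & startsWith(dx, pref)
      sub[hit] <- cat
      unassigned <- unassigned & !hit
    }
  }
  sub[is_case & is.na(sub)] <- "other_mh"

  suicide <- vapply(ec_items, function(v) {
    v <- trimws(v)
    any(startsWith(v, tax$suicide_ecode_prefix))
  }, logical(1))

  encounters$is_case <- is_case
  encounters$subcategory <- sub
  encounters$suicide_flag <- suicide
  encounters
}

#' Apply the study cohort filters
#'
#' Keeps encounters admitted in the analysis months and years, aged within
#' the study range, not scheduled, and carrying a mental-health primary
#' diagnosis.  Filters are applied in a fixed order (calendar, age,
#' scheduled, diagnosis) so the attrition log is comparable across runs.
#' Retained records are assigned an age group; records with unknown sex,
#' race/ethnicity or payer are retained here and excluded only from the
#' corresponding stratified analysis.
#'
#' @param encounters Line-list data frame.
#' @param tax A `dx_taxonomy`.
#' @param years Admission years to keep (default 2005-2011).
#' @param months Admission calendar months to keep (default June-August).
#' @param age_range Inclusive age bounds in years (default c(6, 25)).
#' @param age_breaks Left-closed age-group cut points (default 6, 12, 18 with
#'   upper bound `age_range[2]`), yielding groups 6-11, 12-17, 18-25.
#' @return The retained rows with `age_group`, `subcategory`, `suicide_flag`
#'   columns and an `"attrition"` attribute (named integer vector of removals
#'   per rule plus `n_input`/`n_output`).
#' @export
apply_cohort_filters <- function(encounters, tax = default_taxonomy(),
                                 years = 2005:2011, months = 6:8,
                                 age_range = c(6L, 25L),
                                 age_breaks = c(6L, 12L, 18L)) {
  x <- classify_encounters(encounters, tax)
  n_in <- nrow(x)
  lt <- as.POSIXlt(x$admit_date)
  keep <- (lt$mon + 1L) %in% months & (lt$year + 1900L) %in% years
  n_calendar <- sum(!keep); x <- x[keep, , drop = FALSE]
  keep <- x$age_years >= age_range[1] & x$age_years <= age_range[2]
  n_age <- sum(!keep); x <- x[keep, , drop = FALSE]
  keep <- !x$scheduled
  n_sched <- sum(!keep); x <- x[keep, , drop = FALSE]
  keep <- x$is_case
  n_dx <- sum(!keep); x <- x[keep, , drop = FALSE]

  brk <- c(age_breaks, age_range[2] + 1L)
  labs <- paste0(brk[-length(brk)], "-", brk[-1] - 1L)
  x$age_group <- as.character(cut(x$age_years, breaks = brk, labels = labs,
                                  right = FALSE))
  attr(x, "attrition") <- c(calendar = n_calendar, age = n_age,
                            scheduled = n_sched, diagnosis = n_dx,
                            n_input = n_in, n_output = nrow(x))
  x
}
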
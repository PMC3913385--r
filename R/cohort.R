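# Subject-level data model, exclusion filters, and per-subject aggregation
# of tooth measurements.

.smoking_levels <- c("nonsmoker", "stopped", "smoker")

#' Read a cohort CSV
#'
#' Expected columns: `subject_id`, `group` (`case`/`control`),
#' `maternal_age` (years), `bmi` (kg/m^2, pre-pregnancy), `smoking`
#' (`nonsmoker`/`stopped`/`smoker`), `natural_anterior_teeth` (0--12),
#' `antibiotics_recent` (0/1), `visit_index` (>= 1), `delivery_weeks`
#' (gestational age at delivery; blank allowed). An optional logical
#' `withdrawn` column marks subjects who left before imaging.
#'
#' @param path path to the CSV file.
#' @return a data frame, one row per subject visit.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "maternal_age", "bmi", "smoking",
           "natural_anterior_teeth", "antibiotics_recent", "visit_index")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$antibiotics_recent <- as.logical(df$antibiotics_recent) |
    df$antibiotics_recent == 1
  bad_smoke <- !is.na(df$smoking) & !(df$smoking %in% .smoking_levels)
  if (any(bad_smoke))
    stop("unknown smoking level(s): ",
         paste(unique(df$smoking[bad_smoke]), collapse = ", "))
  if (!"delivery_weeks" %in% names(df)) df$delivery_weeks <- NA_real_
  df$delivery_weeks <- suppressWarnings(as.numeric(df$delivery_weeks))
  df
}

#' Apply the study exclusion rules to a cohort
#'
#' Rows with `visit_index > 1` are dropped first (each subject contributes
#' only their first imaging visit, to avoid observation-induced behaviour
#' change), then subjects are excluded, in order, when they (1) have fewer
#' than 10 natural anterior teeth, (2) recently took antibiotics, (3) are
#' missing BMI, smoking status or age, or (4) withdrew before imaging.
#' Each dropped row is logged once under its first matching reason;
#' retained plus excluded row counts always equal the input count.
#'
#' @param cohort data frame as returned by [read_cohort()].
#' @return list with `retained` (data frame) and `exclusions` (data frame
#'   with columns `subject_id`, `reason`).
#' @export
apply_exclusions <- function(cohort) {
  key <- paste(cohort$subject_id, cohort$visit_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, visit_index) rows: ",
         paste(unique(cohort$subject_id[duplicated(key)]), collapse = ", "))
  withdrawn <- if ("withdrawn" %in% names(cohort))
    isTRUE_vec(cohort$withdrawn) else rep(FALSE, nrow(cohort))

  reason <- rep(NA_character_, nrow(cohort))
  mark <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  mark(cohort$visit_index > 1, "repeat_visit")
  mark(cohort$natural_anterior_teeth < 10, "fewer_than_10_teeth")
  mark(cohort$antibiotics_recent, "recent_antibiotics")
  mark(is.na(cohort$bmi) | is.na(cohort$smoking) | is.na(cohort$maternal_age),
       "missing_covariates")
  mark(withdrawn, "withdrawn")

  keep <- is.na(reason)
  list(
    retained = cohort[keep, , drop = FALSE],
    exclusions = data.frame(subject_id = cohort$subject_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Aggregate per-tooth measurements to subject level
#'
#' Computes the arithmetic mean plaque coverage and mean red-fluorescence
#' elevation over each subject's measured anterior teeth, carrying the
#' subject covariates along.
#'
#' @param cohort retained cohort rows, see [apply_exclusions()].
#' @param measurements data frame with columns `subject_id`, `tooth_id`,
#'   `coverage_pct`, `delta_r_pct` (one row per measured tooth).
#' @return a data frame of subject summaries with columns `subject_id`,
#'   `group`, `mean_coverage_pct`, `mean_delta_r_pct`, `n_teeth_measured`
#'   and the cohort covariates.
#' @export
summarize_subjects <- function(cohort, measurements) {
  need <- c("subject_id", "coverage_pct", "delta_r_pct")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements are missing columns: ", paste(miss, collapse = ", "))
  no_meas <- setdiff(cohort$subject_id, measurements$subject_id)
  if (length(no_meas))
    stop("no tooth measurements for subject(s): ",
         paste(no_meas, collapse = ", "))
  m <- measurements[measurements$subject_id %in% cohort$subject_id, ]
  agg <- do.call(rbind, lapply(split(m, m$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1],
               mean_coverage_pct = mean(d$coverage_pct),
               mean_delta_r_pct = mean(d$delta_r_pct),
               n_teeth_measured = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- merge(cohort, agg, by = "subject_id", sort = FALSE)
  out[order(match(out$subject_id, cohort$subject_id)), , drop = FALSE]
}

#' Classify a delivery by gestational age
#'
#' Half-open bins: `< 28` weeks extreme preterm, `[28, 34)` moderate,
#' `[34, 37)` mild, `>= 37` term; preterm means `< 37` completed weeks.
#' Missing values map to `"unknown"` and are excluded from outcome
#' tabulations.
#'
#' @param delivery_weeks numeric vector of gestational ages (weeks).
#' @return factor with levels `extreme`, `moderate`, `mild`, `term`,
#'   `unknown`.
#' @export
classify_delivery <- function(delivery_weeks) {
  out <- ifelse(is.na(delivery_weeks), "unknown",
         ifelse(delivery_weeks < 28, "extreme",
         ifelse(delivery_weeks < 34, "moderate",
         ifelse(delivery_weeks < 37, "mild", "term"))))
  factor(out, levels = c("extreme", "moderate", "mild", "term", "unknown"))
}
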
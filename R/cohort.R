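# Cohort construction: study entry/exit rules, plausibility filters,
# sex-specific standardization, landmark eligibility and per-landmark
# datasets with 10-year follow-up.

#' Compute study entry and exit for every patient
#'
#' Entry is the latest of: registration date plus 6 months, the practice's
#' acceptable-computer-usage date, the practice's acceptable-mortality-
#' reporting date, the 30th birthday, and the study start.  Exit is the
#' earliest of: first CVD event, transfer out, death, and the study end.
#' Patients are flagged excluded when sex is unknown, entry is not before
#' exit, or entry falls after age 85.  ("6 months" is implemented as half of
#' 365.25 days.)
#'
#' @param registry Registry `data.table`; see [generate_population()] for the
#'   expected columns.
#' @param study_start,study_end Study window (`Date` or string); defaults
#'   1997-01-01 and 2016-01-18.
#' @return A copy of the registry with added columns `entry_date`,
#'   `exit_date`, `entry_age`, `exit_age`, `cvd_age`, `statin_age`,
#'   `diabetes_age`, `bp_med_age`, `excluded`, `exclusion_reason`.
#' @export
compute_study_window <- function(registry, study_start = "1997-01-01",
                                 study_end = "2016-01-18") {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  reg <- copy(as.data.table(registry))
  if (anyNA(reg$birth_date)) {
    stop("missing birth date for patient(s) ",
         paste(head(reg[is.na(birth_date), patient_id]), collapse = ", "))
  }
  if (any(!is.na(reg$transfer_out_date) &
          reg$transfer_out_date < reg$registration_date))
    stop("exit date before registration: data error")
  half_year <- round(DAYS_PER_YEAR / 2)
  reg[, entry_date := pmax(registration_date + half_year,
                           acceptable_computer_usage_date,
                           acceptable_mortality_reporting_date,
                           date_at(30, birth_date),
                           study_start, na.rm = TRUE)]
  reg[, exit_date := pmin(first_cvd_event_date, transfer_out_date,
                          death_date, study_end, na.rm = TRUE)]
  reg[, `:=`(entry_age = age_at(entry_date, birth_date),
             exit_age = age_at(exit_date, birth_date),
             cvd_age = age_at(first_cvd_event_date, birth_date),
             statin_age = age_at(first_statin_date, birth_date),
             diabetes_age = age_at(first_diabetes_date, birth_date),
             bp_med_age = age_at(first_bp_med_date, birth_date))]
  reg[, excluded := FALSE]
  reg[, exclusion_reason := NA_character_]
  reg[!(sex %in% c("male", "female")),
      `:=`(excluded = TRUE, exclusion_reason = "unknown_sex")]
  reg[excluded == FALSE & entry_date >= exit_date,
      `:=`(excluded = TRUE, exclusion_reason = "entry_not_before_exit")]
  reg[excluded == FALSE & entry_age > 85,
      `:=`(excluded = TRUE, exclusion_reason = "entry_after_age_85")]
  reg[]
}

#' Remove biologically implausible measurements
#'
#' Strict-inequality limits: SBP outside \[60, 250\] mm Hg, total cholesterol
#' outside \[1.75, 20\] mmol/L, HDL-C outside \[0.3, 3.1\] mmol/L.  Boundary
#' values are retained.  Smoking values are never filtered.
#'
#' @param measurements Long-format measurement `data.table` with columns
#'   `patient_id`, `marker`, `age`, `value`.
#' @return A list: `measurements` (rows retained) and `removed` (named count
#'   of removed rows per marker).
#' @export
apply_plausibility_filters <- function(measurements) {
  meas <- as.data.table(measurements)
  unknown <- setdiff(unique(meas$marker), MARKERS)
  if (length(unknown)) {
    bad <- which(meas$marker %in% unknown)[1]
    stop("unknown marker '", meas$marker[bad], "' in measurement row ", bad)
  }
  keep <- rep(TRUE, nrow(meas))
  removed <- setNames(integer(length(MARKERS)), MARKERS)
  for (k in names(PLAUSIBLE_RANGE)) {
    lim <- PLAUSIBLE_RANGE[[k]]
    bad <- meas$marker == k & (meas$value < lim[1] | meas$value > lim[2])
    removed[[k]] <- sum(bad)
    keep <- keep & !bad
  }
  list(measurements = meas[keep], removed = removed)
}

#' Sex-specific standardization parameters
#'
#' Mean and standard deviation of SBP, total cholesterol and HDL-C by sex,
#' computed from each patient's first measurement after study entry (so the
#' parameters can be frozen on training data and reused on held-out folds
#' without leakage).
#'
#' @param measurements Filtered measurement table (must contain `age`).
#' @param registry Registry with `entry_age` and `sex`
#'   (from [compute_study_window()]).
#' @return An object of class `std_params`: a `data.table` with columns
#'   `sex`, `marker`, `mean`, `sd`.
#' @export
fit_standardization <- function(measurements, registry) {
  meas <- as.data.table(measurements)[marker %in% STD_MARKERS]
  reg <- as.data.table(registry)[, .(patient_id, sex, entry_age)]
  meas <- reg[meas, on = "patient_id"]
  first <- meas[age >= entry_age][order(age),
                                  .SD[1], by = .(patient_id, marker)]
  params <- first[, .(mean = mean(value), sd = sd(value), n = .N),
                  by = .(sex, marker)]
  if (any(is.na(params$sd)))
    stop("fewer than 2 observations for some sex x marker stratum")
  if (any(params$sd <= 0)) stop("zero standard deviation in standardization")
  setkey(params, sex, marker)
  structure(params, class = c("std_params", class(params)))
}

#' Standardize (or invert) continuous marker values
#'
#' Adds a `value_std` column: `(value - mean) / sd` with the sex-specific
#' parameters for SBP, total cholesterol and HDL-C; smoking is passed
#' through unchanged.
#'
#' @param measurements Measurement table.
#' @param params A [fit_standardization()] object.
#' @param registry Registry supplying `sex` per patient.
#' @return The measurement table with a `value_std` column.
#' @export
standardize <- function(measurements, params, registry) {
  meas <- as.data.table(measurements)
  reg <- as.data.table(registry)[, .(patient_id, sex)]
  meas <- reg[meas, on = "patient_id"]
  meas[, value_std := value]
  p <- as.data.table(params)
  meas[p, on = c("sex", "marker"), value_std := (value - i.mean) / i.sd]
  meas[]
}

#' @rdname standardize
#' @export
unstandardize <- function(measurements, params) {
  meas <- as.data.table(measurements)
  p <- as.data.table(params)
  meas[, value := value_std]
  meas[p, on = c("sex", "marker"), value := value_std * i.sd + i.mean]
  meas[]
}

#' Build the study cohort
#'
#' Applies the study window, the plausibility filters, and the "at least one
#' qualifying measurement between study entry and exit" exclusion, logging
#' counts at every step (flow-diagram style).
#'
#' @inheritParams compute_study_window
#' @param measurements Raw measurement table.
#' @return A list of class `lm_cohort`: `registry` (retained patients, with
#'   window columns), `measurements` (filtered, all ages retained for
#'   history extraction), `flow` (step/count log), `removed` (per-marker
#'   implausible counts), `std_params` (sex-specific standardization fitted
#'   on the retained cohort).
#' @export
build_cohort <- function(registry, measurements,
                         study_start = "1997-01-01",
                         study_end = "2016-01-18") {
  reg <- compute_study_window(registry, study_start, study_end)
  flow <- list(target_population = nrow(reg))
  filt <- apply_plausibility_filters(measurements)
  meas <- filt$measurements
  flow$implausible_measurements_removed <- sum(filt$removed)

  keep <- reg[excluded == FALSE]
  flow$after_window_rules <- nrow(keep)
  # qualifying measurement between entry and exit
  win <- keep[, .(patient_id, entry_age, exit_age)]
  m <- win[meas, on = "patient_id", nomatch = NULL]
  qual <- unique(m[age >= entry_age & age <= exit_age, patient_id])
  keep[!patient_id %in% qual,
       `:=`(excluded = TRUE, exclusion_reason = "no_qualifying_measurement")]
  reg[keep[excluded == TRUE], on = "patient_id",
      `:=`(excluded = TRUE, exclusion_reason = i.exclusion_reason)]
  study <- keep[excluded == FALSE]
  flow$study_sample <- nrow(study)

  meas <- meas[patient_id %in% study$patient_id]
  std <- fit_standardization(meas, study)
  meas <- standardize(meas, std, study)
  setkey(study, patient_id)
  structure(list(registry = study, all_registry = reg, measurements = meas,
                 flow = flow, removed = filt$removed, std_params = std),
            class = "lm_cohort")
}

#' Landmark-age eligibility
#'
#' A patient is eligible at landmark age `s` when registered and under
#' follow-up (`entry_age <= s < exit_age`), free of CVD at `s`, and
#' statin-free at `s`.  An event or statin prescription at exactly `s`
#' renders the patient ineligible, which guarantees strictly positive
#' follow-up time.
#'
#' @param registry Registry with window columns.
#' @param s Landmark age (years).
#' @return Logical vector, one element per registry row.
#' @export
landmark_eligible <- function(registry, s) {
  reg <- as.data.table(registry)
  reg$entry_age <= s & s < reg$exit_age &
    (is.na(reg$cvd_age) | reg$cvd_age > s) &
    (is.na(reg$statin_age) | reg$statin_age > s)
}

#' Build a landmark dataset
#'
#' For each patient eligible at `s`: the measurement history restricted to
#' ages in \[30, s\] (both boundaries inclusive), carry-forward diabetes and
#' BP-treatment flags at `s`, and the 10-year-capped follow-up outcome
#' (`follow_time = min(exit_age - s, horizon)`, `event = 1` iff the first
#' CVD event occurs within the horizon).
#'
#' @param s Landmark age; must belong to `grid`.
#' @param cohort An [build_cohort()] object (or a list with standardized
#'   `measurements` and windowed `registry`).
#' @param grid Allowed landmark ages (default 40, 45, ..., 85).
#' @param horizon Prediction horizon in years (default 10).
#' @return A list of class `landmark_dataset`: `s`, `info` (one row per
#'   eligible patient with flags and outcome) and `history` (long-format
#'   measurements with `t_lm = age - s` and the BP-medication indicator at
#'   measurement time).
#' @export
build_landmark_dataset <- function(s, cohort, grid = seq(40, 85, by = 5),
                                   horizon = 10) {
  if (!s %in% grid)
    stop("landmark age ", s, " is outside the configured grid")
  reg <- cohort$registry
  elig <- reg[landmark_eligible(reg, s)]
  info <- elig[, .(
    patient_id, practice_id, sex, lm_age = s,
    diabetes = as.numeric(!is.na(diabetes_age) & diabetes_age <= s),
    bp_med = as.numeric(!is.na(bp_med_age) & bp_med_age <= s),
    follow_time = pmin(exit_age - s, horizon),
    event = as.numeric(!is.na(cvd_age) & cvd_age <= s + horizon))]
  hist <- cohort$measurements[patient_id %in% info$patient_id &
                                age >= 30 & age <= s]
  hist <- elig[, .(patient_id, bp_med_age)][hist, on = "patient_id"]
  hist[, `:=`(t_lm = age - s,
              bp_med_at_meas = as.numeric(!is.na(bp_med_age) &
                                            bp_med_age <= age))]
  hist[, bp_med_age := NULL]
  setkey(hist, patient_id, marker, age)
  structure(list(s = s, info = info, history = hist, horizon = horizon),
            class = "landmark_dataset")
}

#' Last-observed and cumulative-mean marker summaries
#'
#' Comparator covariates: `last_observed()` takes, per patient and marker,
#' the standardized value at the latest measurement age at or before the
#' landmark (ties broken by record order, latest wins); `cumulative_mean()`
#' averages all historical standardized values.  Both are `NA` for patients
#' with no history rows for the marker.
#'
#' @param ld A [build_landmark_dataset()] object.
#' @return A wide `data.table`: `patient_id` plus one column per marker.
#' @export
last_observed <- function(ld) {
  wide_summary(ld, function(v) v[length(v)])
}

#' @rdname last_observed
#' @export
cumulative_mean <- function(ld) {
  wide_summary(ld, mean)
}

wide_summary <- function(ld, f) {
  h <- ld$history[order(patient_id, marker, age)]
  sm <- h[, .(v = f(value_std)), by = .(patient_id, marker)]
  out <- dcast(sm, patient_id ~ marker, value.var = "v")
  for (k in setdiff(MARKERS, names(out))) out[, (k) := NA_real_]
  all <- data.table(patient_id = ld$info$patient_id)
  out <- out[all, on = "patient_id"]
  setcolorder(out, c("patient_id", MARKERS))
  out[]
}

#' Crude incidence rate per 1,000 person-years
#'
#' @param cases Number of incident events.
#' @param person_years Total follow-up time in years (> 0).
#' @return The rate `1000 * cases / person_years`, rounded to 1 decimal.
#' @export
incidence_rate <- function(cases, person_years) {
  if (any(person_years <= 0)) stop("person_years must be > 0")
  round(1000 * cases / person_years, 1)
}

#' Percentage of a count, rounded to whole percent
#'
#' Convention used in cohort flow summaries (e.g. the share of the target
#' population with at least one marker measurement).
#'
#' @param count,total Nonnegative counts, `total > 0`.
#' @return `round(100 * count / total)`.
#' @export
cohort_percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0")
  round(100 * count / total)
}

#' Crude incidence summary of a cohort registry
#'
#' Events and person-years between study entry and exit, overall, by sex and
#' by age-at-entry band.
#'
#' @param registry Windowed registry (retained patients).
#' @return A `data.table` with columns `group`, `level`, `cases`,
#'   `person_years`, `rate_per_1000py`.
#' @export
incidence_summary <- function(registry) {
  reg <- as.data.table(registry)
  reg[, `:=`(py = exit_age - entry_age,
             case = as.numeric(!is.na(cvd_age)))]
  band <- cut(reg$entry_age, breaks = seq(30, 90, by = 5), right = FALSE)
  one <- function(group, level, idx) {
    data.table(group = group, level = level,
               cases = sum(reg$case[idx]),
               person_years = sum(reg$py[idx]),
               rate_per_1000py = incidence_rate(sum(reg$case[idx]),
                                                sum(reg$py[idx])))
  }
  out <- list(one("overall", "all", seq_len(nrow(reg))))
  for (sx in c("male", "female"))
    out[[length(out) + 1]] <- one("sex", sx, which(reg$sex == sx))
  for (b in levels(band)) {
    idx <- which(band == b)
    if (length(idx)) out[[length(out) + 1]] <- one("entry_age", b, idx)
  }
  rbindlist(out)
}
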
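# Cohort rules: entry/exit dates, plausibility filters, standardization,
# landmark eligibility, history windows and descriptive rates.

test_that("study entry is the latest of the five entry rules", {
  # study start binds
  p1 <- mk_patient(registration = "1995-06-01", acu = "1996-01-01",
                   amr = "1996-06-01", birth = "1960-01-01")
  w1 <- compute_study_window(p1)
  expect_equal(w1$entry_date, as.Date("1997-01-01"))
  # registration + 6 months binds
  p2 <- mk_patient(registration = "2001-03-01", acu = "1996-01-01",
                   amr = "1996-06-01", birth = "1960-01-01")
  w2 <- compute_study_window(p2)
  expect_equal(w2$entry_date, as.Date("2001-03-01") + round(365.25 / 2))
  # 30th birthday binds
  p3 <- mk_patient(birth = "1975-07-01", registration = "1998-01-01")
  w3 <- compute_study_window(p3)
  expect_equal(w3$entry_date, date_at(30, as.Date("1975-07-01")))
})

test_that("study exit is the earliest exit rule and drives exclusions", {
  p <- mk_patient(transfer = "2005-05-05")
  w <- compute_study_window(p)
  expect_equal(w$exit_date, as.Date("2005-05-05"))
  # CVD event before transfer becomes the exit
  p2 <- mk_patient(transfer = "2005-05-05", cvd = "2003-01-01")
  expect_equal(compute_study_window(p2)$exit_date, as.Date("2003-01-01"))
  # default exit is the administrative end of data
  expect_equal(compute_study_window(mk_patient())$exit_date,
               as.Date("2016-01-18"))
  # exclusion reasons
  px <- rbind(mk_patient(patient_id = 1, sex = "unknown"),
              mk_patient(patient_id = 2, transfer = "1996-01-01",
                         registration = "1990-01-01"),
              mk_patient(patient_id = 3, birth = "1910-01-01"))
  wx <- compute_study_window(px)
  expect_equal(wx$exclusion_reason,
               c("unknown_sex", "entry_not_before_exit", "entry_after_age_85"))
})

test_that("plausibility limits are strict inequalities with boundaries retained", {
  m <- data.table(
    patient_id = 1L,
    marker = c("sbp", "sbp", "sbp", "hdlc", "hdlc", "tchol", "smoking"),
    age = 50, value = c(59, 60, 251, 3.2, 3.1, 5.5, 1))
  r <- apply_plausibility_filters(m)
  expect_equal(r$removed[["sbp"]], 2L)   # 59 and 251 removed, 60 kept
  expect_equal(r$removed[["hdlc"]], 1L)  # 3.2 removed, boundary 3.1 kept
  expect_equal(r$removed[["tchol"]], 0L) # interior point kept
  expect_true(all(c(60, 3.1, 5.5, 1) %in% r$measurements$value))
  expect_error(apply_plausibility_filters(
    data.table(patient_id = 1L, marker = "ldl", age = 50, value = 3)),
    "unknown marker 'ldl'")
})

test_that("standardization centers on sex-specific means and round-trips", {
  reg <- rbind(mk_patient(1, sex = "male"), mk_patient(2, sex = "male"),
               mk_patient(3, sex = "female"), mk_patient(4, sex = "female"))
  reg <- compute_study_window(reg)
  m <- data.table(patient_id = rep(1:4, each = 2), marker = "sbp",
                  age = rep(c(48, 52), 4),
                  value = c(120, 140, 110, 150, 125, 135, 115, 145))
  par <- fit_standardization(m, reg)
  # first-post-entry values: 120,110 (male) 125,115 (female)
  expect_equal(par[sex == "male" & marker == "sbp", mean], 115)
  sd_m <- sd(c(120, 110))
  z <- standardize(m, par, reg)
  expect_equal(z[patient_id == 1 & age == 48, value_std],
               (120 - 115) / sd_m)
  # value at the sex mean -> 0; mean + sd -> 1
  m2 <- data.table(patient_id = 1L, marker = "sbp", age = 50,
                   value = c(115, 115 + sd_m))
  expect_equal(standardize(m2, par, reg)$value_std, c(0, 1))
  # algebraic round trip
  back <- unstandardize(z, par)
  expect_equal(back$value, m$value, tolerance = 1e-12)
  # zero sd errors
  m3 <- data.table(patient_id = c(1L, 2L), marker = "sbp", age = 50,
                   value = c(120, 120))
  expect_error(fit_standardization(m3, reg), "zero standard deviation")
})

test_that("landmark eligibility applies registration, CVD and statin rules", {
  reg <- rbind(
    mk_patient(1, birth = "1950-01-01", registration = "1990-06-01",
               statin = "2002-01-10"),                     # statin at ~52
    mk_patient(2, birth = "1950-01-01", registration = "1990-06-01"),
    mk_patient(3, birth = "1950-01-01", registration = "1990-06-01",
               cvd = "2008-01-05"))                        # event at ~58
  w <- compute_study_window(reg)
  expect_false(landmark_eligible(w[1], 55))   # statin before 55
  expect_true(landmark_eligible(w[2], 60))
  expect_false(landmark_eligible(w[3], 60))   # event before 60
  expect_true(landmark_eligible(w[3], 55))    # event after 55: still at risk
})

test_that("landmark datasets cap follow-up at the horizon and window history at [30, s]", {
  reg <- rbind(
    mk_patient(1, birth = "1945-01-01", registration = "1980-01-01"),
    # transfers out 4.2 years after the landmark age 60 (birth 1945 -> 2009-03)
    mk_patient(2, birth = "1945-01-01", registration = "1980-01-01",
               transfer = format(date_at(64.2, as.Date("1945-01-01")))),
    mk_patient(3, birth = "1945-01-01", registration = "1980-01-01",
               cvd = format(date_at(58, as.Date("1945-01-01")))))
  # entry ages are ~52 (study start 1997, birth 1945); each patient needs a
  # qualifying measurement between entry and exit, and standardization needs
  # at least two first-post-entry values per sex
  m <- data.table(patient_id = c(1L, 1L, 1L, 2L, 3L),
                  marker = "sbp",
                  age = c(29.5, 45, 53, 53.5, 53),
                  value = c(130, 132, 134, 128, 126))
  co <- build_cohort(reg, m)
  ld <- build_landmark_dataset(55, co)
  # patient 3 had the event at 58 (< 55 + 10): event row with 3y follow-up
  i3 <- ld$info[patient_id == 3]
  expect_equal(i3$event, 1)
  expect_equal(i3$follow_time, 3, tolerance = 0.01)
  # patient 1 is never censored before 55+10: capped at the horizon
  i1 <- ld$info[patient_id == 1]
  expect_equal(i1$event, 0)
  expect_equal(i1$follow_time, 10)
  # patient 2: censored 9.2y after s=55 -> within horizon, no event
  i2 <- ld$info[patient_id == 2]
  expect_equal(i2$event, 0)
  expect_equal(i2$follow_time, 9.2, tolerance = 0.01)
  # the age-29.5 measurement is excluded from history; ages 45 and 53 remain
  expect_false(any(ld$history$age < 30))
  expect_setequal(ld$history[patient_id == 1, age], c(45, 53))
  expect_error(build_landmark_dataset(62, co), "outside the configured grid")
})

test_that("no patient enters a landmark dataset at an age where it is ineligible", {
  ehr <- simulate_ehr(synth_config(n_patients = 250), seed = 21)
  co <- build_cohort(ehr$registry, ehr$measurements)
  for (s in c(45, 60, 75)) {
    ld <- build_landmark_dataset(s, co)
    reg <- co$registry[J(ld$info$patient_id)]
    expect_true(all(landmark_eligible(reg, s)))
    expect_true(all(ld$info$follow_time > 0 & ld$info$follow_time <= 10))
    # an event indicator never claims follow-up beyond the event age
    ev <- ld$info[event == 1]
    cv <- reg[J(ev$patient_id), cvd_age]
    expect_true(all(abs(pmin(cv - s, 10) - ev$follow_time) < 1e-9))
  }
})

test_that("last-observed and cumulative-mean summaries handle missing markers", {
  info <- data.table(patient_id = 1:3, practice_id = 1L, sex = "male",
                     lm_age = 55, diabetes = 0, bp_med = 0,
                     follow_time = 10, event = 0)
  hist <- data.table(
    patient_id = c(1L, 1L, 1L, 2L),
    marker = c("sbp", "sbp", "sbp", "tchol"),
    age = c(45, 50, 54, 52),
    value_std = c(5, 6, 7, 130), t_lm = c(-10, -5, -1, -3),
    bp_med_at_meas = 0)
  ld <- mk_landmark_dataset(info, hist, s = 55)
  lo <- last_observed(ld)
  cm <- cumulative_mean(ld)
  expect_equal(lo[patient_id == 1, sbp], 7)
  expect_equal(cm[patient_id == 1, sbp], 6)
  # single measurement: both equal it
  expect_equal(lo[patient_id == 2, tchol], 130)
  expect_equal(cm[patient_id == 2, tchol], 130)
  # empty history: missing for both
  expect_true(is.na(lo[patient_id == 3, sbp]))
  expect_true(all(is.na(unlist(cm[patient_id == 3, .(smoking, sbp, tchol, hdlc)]))))
})

test_that("incidence rates and cohort percentages follow the reporting conventions", {
  expect_equal(incidence_rate(0, 1000), 0.0)
  expect_equal(incidence_rate(50, 10000), 5.0)
  expect_error(incidence_rate(5, 0), "person_years")
  expect_equal(cohort_percent(1, 3), 33)
  expect_error(cohort_percent(1, 0), "total")
})

test_that("cohort flow counts are nested: restricted within study within target", {
  ehr <- simulate_ehr(synth_config(n_patients = 300), seed = 22)
  co <- build_cohort(ehr$registry, ehr$measurements)
  expect_lte(co$flow$study_sample, co$flow$after_window_rules)
  expect_lte(co$flow$after_window_rules, co$flow$target_population)
  # restricted sample (>=1 measurement of every marker) is a subset
  ld <- build_landmark_dataset(60, co)
  lo <- last_observed(ld)
  restricted <- lo[complete.cases(lo), patient_id]
  expect_true(all(restricted %in% co$registry$patient_id))
  expect_lte(length(restricted), nrow(ld$info))
})
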
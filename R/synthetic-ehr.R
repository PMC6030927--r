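# Synthetic primary-care EHR generator.
#
# Emulates the data structures the two-stage landmark model consumes: a
# patient registry with registration/transfer/death dates and first-occurrence
# dates for diabetes, blood-pressure-lowering medication, statins and CVD
# events; and a long-format measurement table in which each of four risk
# markers (smoking status, SBP, total cholesterol, HDL-C) is observed
# sporadically at marker-specific Poisson visit rates.  Person-level marker
# trajectories share correlated random intercepts, treatment initiation
# shifts SBP, and CVD event times follow a Gompertz-baseline proportional
# hazards model on the true (error-free) current covariate values.

#' Configuration for the synthetic EHR generator
#'
#' Parameters of the data-generating process.  Marker dynamics are specified
#' on a standardized (z-score) scale: the latent error-free value of marker
#' `k` for patient `i` at age `a` is
#' `z_ik(a) = beta0_k + beta1_k (a - 30) + gamma 1[on BP med, k = sbp] + b_ik`,
#' with `b_i ~ MVN(0, G)` and observation noise `N(0, sigma2_k)`.  Observed
#' values are emitted in natural units as `location + scale * z_obs`
#' (sex-specific), except smoking, which is emitted either as the continuous
#' latent value (`smoking_mode = "linear-gaussian"`, the default, matching
#' the multivariate-normal working assumption of stage 1) or dichotomised at
#' `smoking_threshold` (`"bernoulli-threshold"`).
#'
#' The CVD hazard at age `a` is
#' `h(a) = rate30_sex * exp(log_slope_sex * (a - 30) + sum_k theta_k z_ik(a)
#'  + theta_diab D_i(a) + theta_bp B_i(a))`,
#' which is piecewise log-linear in age and is inverted exactly interval by
#' interval when event ages are drawn.
#'
#' Default values reproduce study conditions a primary-care CVD cohort would
#' show: mean inter-measurement gaps of about 1.1y (smoking), 0.5y (SBP),
#' 1.1y (total cholesterol) and 1.2y (HDL-C); roughly 7% 10-year event
#' fractions at ages around 60; and per-SD hazard ratios of conventional
#' magnitude for the four markers.
#'
#' @param n_patients Number of patients (>= 1).
#' @param n_practices Number of general practices; patients are assigned
#'   round-robin so practice sizes are balanced.
#' @param birth_year_range Two integers, inclusive range of birth years.
#' @param registration_age_mean,registration_age_sd,registration_age_range
#'   Truncated-normal distribution of age at practice registration.
#' @param transfer_out_rate Constant hazard (per year) of transferring out.
#' @param death_rate30,death_log_slope Gompertz hazard of non-CVD death:
#'   rate at age 30 and log-slope per year.
#' @param visit_rates Named vector, Poisson visit rate per year for each of
#'   the four markers.  A zero rate means the marker is never measured.
#' @param true_beta0,true_beta1 Named vectors: per-marker latent intercept at
#'   age 30 and slope per year, standardized units.
#' @param bp_med_effect_on_sbp Shift (standardized units) of latent SBP after
#'   initiation of blood-pressure-lowering medication.
#' @param true_G 4x4 symmetric positive-semidefinite covariance of the
#'   random intercepts, marker order `c("smoking","sbp","tchol","hdlc")`.
#' @param true_sigma2 Named vector of residual (measurement-error) variances.
#' @param smoking_mode `"linear-gaussian"` or `"bernoulli-threshold"`.
#' @param smoking_threshold Threshold on the noisy latent scale for the
#'   Bernoulli emission mode.
#' @param marker_location,marker_scale Per-sex named lists mapping the latent
#'   standardized scale to natural units.
#' @param diabetes_rate,bp_med_rate,statin_rate Exponential initiation rates
#'   per year from age 30.
#' @param baseline_hazard Per-sex list with `rate30` and `log_slope` of the
#'   Gompertz CVD baseline hazard.
#' @param true_log_hazard_ratios Named vector of log hazard ratios applied to
#'   the latent standardized marker values and to the diabetes and BP-med
#'   carry-forward flags.
#' @param implausible_rate Small probability that a continuous measurement is
#'   replaced by a biologically implausible value, to exercise the
#'   plausibility filters downstream.
#' @param practice_year_range Range of calendar years for the practice-level
#'   acceptable-computer-usage and acceptable-mortality-reporting dates.
#' @param study_end Administrative end of data collection (`Date` or string).
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_patients = 2000L,
                         n_practices = 10L,
                         birth_year_range = c(1930L, 1978L),
                         registration_age_mean = 44,
                         registration_age_sd = 14,
                         registration_age_range = c(25, 84),
                         transfer_out_rate = 0.045,
                         death_rate30 = 2e-4,
                         death_log_slope = 0.085,
                         visit_rates = c(smoking = 1 / 1.1, sbp = 1 / 0.5,
                                         tchol = 1 / 1.1, hdlc = 1 / 1.2),
                         true_beta0 = c(smoking = 0.22, sbp = -0.48,
                                        tchol = -0.44, hdlc = 0.11),
                         true_beta1 = c(smoking = -0.010, sbp = 0.022,
                                        tchol = 0.020, hdlc = -0.005),
                         bp_med_effect_on_sbp = -0.45,
                         true_G = default_G(),
                         true_sigma2 = c(smoking = 0.15, sbp = 0.45,
                                         tchol = 0.30, hdlc = 0.25),
                         smoking_mode = c("linear-gaussian",
                                          "bernoulli-threshold"),
                         smoking_threshold = 0.5,
                         marker_location = list(
                           male   = c(smoking = 0.31, sbp = 136, tchol = 5.45, hdlc = 1.25),
                           female = c(smoking = 0.27, sbp = 133, tchol = 5.55, hdlc = 1.50)),
                         marker_scale = list(
                           male   = c(smoking = 0.15, sbp = 21, tchol = 1.10, hdlc = 0.35),
                           female = c(smoking = 0.15, sbp = 21, tchol = 1.10, hdlc = 0.40)),
                         diabetes_rate = 0.005,
                         bp_med_rate = 0.020,
                         statin_rate = 0.012,
                         baseline_hazard = list(
                           male   = c(rate30 = 1.2e-3, log_slope = 0.065),
                           female = c(rate30 = 0.8e-3, log_slope = 0.065)),
                         true_log_hazard_ratios = c(smoking = 0.55, sbp = 0.30,
                                                    tchol = 0.22, hdlc = -0.28,
                                                    diabetes = 0.55, bp_med = 0.15),
                         implausible_rate = 0.002,
                         practice_year_range = c(1994L, 2000L),
                         study_end = "2016-01-18") {
  smoking_mode <- match.arg(smoking_mode)
  cfg <- list(
    n_patients = as.integer(n_patients), n_practices = as.integer(n_practices),
    birth_year_range = birth_year_range,
    registration_age_mean = registration_age_mean,
    registration_age_sd = registration_age_sd,
    registration_age_range = registration_age_range,
    transfer_out_rate = transfer_out_rate,
    death_rate30 = death_rate30, death_log_slope = death_log_slope,
    visit_rates = visit_rates[MARKERS],
    true_beta0 = true_beta0[MARKERS], true_beta1 = true_beta1[MARKERS],
    bp_med_effect_on_sbp = bp_med_effect_on_sbp,
    true_G = true_G, true_sigma2 = true_sigma2[MARKERS],
    smoking_mode = smoking_mode, smoking_threshold = smoking_threshold,
    marker_location = marker_location, marker_scale = marker_scale,
    diabetes_rate = diabetes_rate, bp_med_rate = bp_med_rate,
    statin_rate = statin_rate,
    baseline_hazard = baseline_hazard,
    true_log_hazard_ratios = true_log_hazard_ratios,
    implausible_rate = implausible_rate,
    practice_year_range = practice_year_range,
    study_end = as.Date(study_end))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

#' Default random-intercept covariance of the generator
#'
#' Variance 0.55 per marker (standardized scale) with modest cross-marker
#' correlations: cholesterol fractions negatively correlated, smoking
#' negatively correlated with HDL-C.
#' @return A named 4x4 covariance matrix.
#' @export
default_G <- function() {
  C <- diag(4)
  dimnames(C) <- list(MARKERS, MARKERS)
  C["smoking", "sbp"] <- C["sbp", "smoking"] <- 0.05
  C["smoking", "tchol"] <- C["tchol", "smoking"] <- 0.10
  C["smoking", "hdlc"] <- C["hdlc", "smoking"] <- -0.25
  C["sbp", "tchol"] <- C["tchol", "sbp"] <- 0.15
  C["sbp", "hdlc"] <- C["hdlc", "sbp"] <- -0.10
  C["tchol", "hdlc"] <- C["hdlc", "tchol"] <- -0.20
  v <- rep(0.55, 4)
  C * tcrossprod(sqrt(v))
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1L, cfg$n_practices >= 1L)
  if (any(cfg$visit_rates < 0) || cfg$transfer_out_rate < 0 ||
      cfg$diabetes_rate < 0 || cfg$bp_med_rate < 0 || cfg$statin_rate < 0)
    stop("all rates must be >= 0")
  G <- cfg$true_G
  if (!isTRUE(all.equal(G, t(G), tolerance = 1e-10)))
    stop("true_G must be symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("true_G must be positive semidefinite")
  if (any(cfg$true_sigma2 <= 0)) stop("true_sigma2 must be > 0")
  invisible(cfg)
}

# PSD square root of G tolerating semidefiniteness (e.g. G = 0)
psd_chol <- function(G) {
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(G)) %*% t(ev$vectors)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# Gompertz first-passage age from age 30: hazard r30 * exp(slope*(a-30))
rgompertz_age <- function(r30, slope) {
  if (r30 <= 0) return(Inf)
  e <- rexp(1L)
  if (abs(slope) < 1e-12) return(30 + e / r30)
  u <- 1 + slope * e / r30
  if (u <= 0) return(Inf)
  30 + log(u) / slope
}

#' Generate the synthetic patient registry and measurement table
#'
#' Draws demographics, registration, transfer-out, non-CVD death, treatment
#' initiation ages and per-marker sporadic measurements for every patient.
#' CVD events are added afterwards by [generate_outcomes()]; use
#' [simulate_ehr()] to run both steps.  Each patient is generated from a
#' deterministic substream of `seed`, so the first `k` patients are identical
#' for any `n_patients >= k`.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed.
#' @return A list of class `synth_ehr` with elements `registry`,
#'   `measurements`, `practices`, `truth` (per-patient true random intercepts
#'   and latent ages, used by tests and by [generate_outcomes()]) and
#'   `config`.
#' @export
generate_population <- function(config, seed) {
  validate_synth_config(config)
  seed <- as.integer(seed)
  set.seed(seed)
  P <- config$n_practices
  yr <- config$practice_year_range
  practices <- data.table(
    practice_id = seq_len(P),
    acceptable_computer_usage_date =
      as.Date(sprintf("%d-01-01", sample(yr[1]:yr[2], P, replace = TRUE))) +
      sample(0:364, P, replace = TRUE),
    acceptable_mortality_reporting_date =
      as.Date(sprintf("%d-01-01", sample(yr[1]:yr[2], P, replace = TRUE))) +
      sample(0:364, P, replace = TRUE))

  Lg <- psd_chol(config$true_G)
  admin_end <- config$study_end
  n <- config$n_patients
  reg_list <- vector("list", n)
  meas_list <- vector("list", n)
  truth_list <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(patient_seed(seed, i, 0L))
    sex <- if (runif(1) < 0.52) "male" else "female"
    by <- sample(config$birth_year_range[1]:config$birth_year_range[2], 1L)
    birth <- as.Date(sprintf("%d-01-01", by)) + sample(0:364, 1L)
    reg_age <- rtruncnorm1(config$registration_age_mean,
                           config$registration_age_sd,
                           config$registration_age_range[1],
                           config$registration_age_range[2])
    transfer_age <- if (config$transfer_out_rate > 0)
      reg_age + rexp(1L, config$transfer_out_rate) else Inf
    death_age <- rgompertz_age(config$death_rate30, config$death_log_slope)
    admin_age <- age_at(admin_end, birth)
    cens_age <- min(transfer_age, death_age, admin_age)

    b <- as.numeric(Lg %*% rnorm(4L))
    names(b) <- MARKERS
    diabetes_age <- if (config$diabetes_rate > 0) 30 + rexp(1L, config$diabetes_rate) else Inf
    bp_med_age <- if (config$bp_med_rate > 0) 30 + rexp(1L, config$bp_med_rate) else Inf
    statin_age <- if (config$statin_rate > 0) 30 + rexp(1L, config$statin_rate) else Inf

    loc <- config$marker_location[[sex]]
    scl <- config$marker_scale[[sex]]
    rows <- list()
    if (cens_age > reg_age) {
      span <- cens_age - reg_age
      for (k in MARKERS) {
        rate <- config$visit_rates[[k]]
        if (rate <= 0) next
        nk <- rpois(1L, rate * span)
        if (nk == 0L) next
        ages <- sort(reg_age + runif(nk) * span)
        z <- config$true_beta0[[k]] + config$true_beta1[[k]] * (ages - 30) +
          b[[k]] +
          if (k == "sbp") config$bp_med_effect_on_sbp * (ages >= bp_med_age) else 0
        zobs <- z + rnorm(nk, sd = sqrt(config$true_sigma2[[k]]))
        if (k == "smoking") {
          val <- if (config$smoking_mode == "bernoulli-threshold")
            as.numeric(zobs > config$smoking_threshold)
          else loc[[k]] + scl[[k]] * zobs
        } else {
          val <- loc[[k]] + scl[[k]] * zobs
          if (config$implausible_rate > 0) {
            bad <- runif(nk) < config$implausible_rate
            if (any(bad)) {
              lim <- PLAUSIBLE_RANGE[[k]]
              val[bad] <- ifelse(runif(sum(bad)) < 0.5,
                                 lim[1] * 0.5, lim[2] * 1.5)
            }
          }
        }
        rows[[k]] <- data.table(patient_id = i, marker = k, age = ages,
                                value = val)
      }
    }
    meas_list[[i]] <- if (length(rows)) rbindlist(rows) else NULL

    reg_list[[i]] <- data.table(
      patient_id = i,
      practice_id = ((i - 1L) %% P) + 1L,
      sex = sex,
      birth_date = birth,
      registration_date = date_at(reg_age, birth),
      transfer_out_date = if (is.finite(transfer_age) && transfer_age < min(death_age, admin_age))
        date_at(transfer_age, birth) else as.Date(NA),
      death_date = if (is.finite(death_age) && death_age < min(transfer_age, admin_age))
        date_at(death_age, birth) else as.Date(NA),
      first_diabetes_date = if (diabetes_age < cens_age) date_at(diabetes_age, birth) else as.Date(NA),
      first_bp_med_date = if (bp_med_age < cens_age) date_at(bp_med_age, birth) else as.Date(NA),
      first_statin_date = if (statin_age < cens_age) date_at(statin_age, birth) else as.Date(NA),
      first_cvd_event_date = as.Date(NA))
    truth_list[[i]] <- data.table(
      patient_id = i, sex = sex,
      b_smoking = b[["smoking"]], b_sbp = b[["sbp"]],
      b_tchol = b[["tchol"]], b_hdlc = b[["hdlc"]],
      reg_age = reg_age, cens_age = cens_age,
      diabetes_age = diabetes_age, bp_med_age = bp_med_age,
      statin_age = statin_age)
  }

  registry <- rbindlist(reg_list)
  registry <- practices[registry, on = "practice_id"]
  setcolorder(registry, c("patient_id", "practice_id", "sex", "birth_date"))
  setkey(registry, patient_id)
  measurements <- rbindlist(Filter(Negate(is.null), meas_list))
  if (nrow(measurements) == 0L)
    measurements <- data.table(patient_id = integer(), marker = character(),
                               age = numeric(), value = numeric())
  measurements[registry, on = "patient_id", date := date_at(age, i.birth_date)]
  structure(list(registry = registry, measurements = measurements,
                 practices = practices, truth = rbindlist(truth_list),
                 config = config, seed = seed),
            class = "synth_ehr")
}

# piecewise log-linear cumulative hazard inversion on [a0, a1] with
# log h(a) = c0 + c1 * a; returns the event age consuming `e` units of
# cumulative hazard, or Inf if the interval's hazard mass is below e
invert_interval <- function(c0, c1, a0, a1, e) {
  if (!is.finite(c0)) return(list(age = Inf, used = 0))
  if (abs(c1) < 1e-12) {
    H <- exp(c0) * (a1 - a0)
    if (H >= e) return(list(age = a0 + e / exp(c0), used = e))
    return(list(age = Inf, used = H))
  }
  H <- exp(c0) * (exp(c1 * a1) - exp(c1 * a0)) / c1
  if (H >= e) {
    age <- log(exp(c1 * a0) + c1 * e * exp(-c0)) / c1
    return(list(age = age, used = e))
  }
  list(age = Inf, used = H)
}

#' Draw CVD event ages and finalize study exit
#'
#' Simulates each patient's first CVD event from a proportional-hazards model
#' with a sex-specific Gompertz baseline and the patient's true latent
#' covariate path (error-free marker values plus carry-forward diabetes and
#' BP-medication flags).  Because the latent markers are linear in age, the
#' log hazard is piecewise linear between treatment-initiation ages and the
#' event age is drawn by exact interval-by-interval inversion of the
#' cumulative hazard.  Measurements after study exit are truncated so the
#' emitted tables respect exit ordering.
#'
#' @param pop A `synth_ehr` list from [generate_population()].
#' @param seed Integer seed (independent of the population substreams).
#' @return The `synth_ehr` list with `first_cvd_event_date` filled in and
#'   measurements truncated at exit.
#' @export
generate_outcomes <- function(pop, seed) {
  config <- pop$config
  registry <- copy(pop$registry)
  truth <- pop$truth
  theta <- config$true_log_hazard_ratios
  event_age <- rep(NA_real_, nrow(registry))

  for (i in seq_len(nrow(registry))) {
    set.seed(patient_seed(seed, i, 1L))
    tr <- truth[i]
    stopifnot(tr$patient_id == registry$patient_id[i])
    sexi <- tr$sex
    bh <- config$baseline_hazard[[sexi]]
    if (bh[["rate30"]] <= 0) next
    cens <- tr$cens_age
    if (cens <= 30) next
    b <- c(tr$b_smoking, tr$b_sbp, tr$b_tchol, tr$b_hdlc)
    names(b) <- MARKERS
    # breakpoints where carry-forward flags switch
    brk <- sort(unique(c(30, pmin(pmax(c(tr$diabetes_age, tr$bp_med_age), 30), cens), cens)))
    brk <- brk[brk <= cens]
    if (brk[length(brk)] < cens) brk <- c(brk, cens)
    e <- rexp(1L)
    hit <- Inf
    for (j in seq_len(length(brk) - 1L)) {
      a0 <- brk[j]; a1 <- brk[j + 1L]
      if (a1 <= a0) next
      amid <- (a0 + a1) / 2
      diab <- as.numeric(amid >= tr$diabetes_age)
      bp <- as.numeric(amid >= tr$bp_med_age)
      # latent z_k(a) = beta0 + beta1 (a-30) + b_k (+ gamma * bp for sbp)
      z0 <- config$true_beta0 + b - 30 * config$true_beta1
      z0[["sbp"]] <- z0[["sbp"]] + config$bp_med_effect_on_sbp * bp
      c0 <- log(bh[["rate30"]]) - 30 * bh[["log_slope"]] +
        sum(theta[MARKERS] * z0) + theta[["diabetes"]] * diab +
        theta[["bp_med"]] * bp
      c1 <- bh[["log_slope"]] + sum(theta[MARKERS] * config$true_beta1)
      res <- invert_interval(c0, c1, a0, a1, e)
      if (is.finite(res$age)) { hit <- res$age; break }
      e <- e - res$used
    }
    if (is.finite(hit) && hit < cens) event_age[i] <- hit
  }

  has_ev <- !is.na(event_age)
  registry[has_ev,
           first_cvd_event_date := date_at(event_age[has_ev], birth_date)]
  # exit ordering: truncate measurements at exit (event/transfer/death/admin)
  exit_age_v <- pmin(ifelse(has_ev, event_age, Inf), truth$cens_age)
  meas <- copy(pop$measurements)
  if (nrow(meas)) {
    meas <- meas[age <= exit_age_v[patient_id]]
  }
  out <- pop
  out$registry <- registry
  out$measurements <- meas
  out$truth <- copy(truth)[, `:=`(event_age = event_age, exit_age = exit_age_v)]
  out
}

#' Simulate a complete synthetic EHR extract
#'
#' Runs [generate_population()] and [generate_outcomes()] under one seed.
#'
#' @inheritParams generate_population
#' @return A `synth_ehr` list; see [generate_population()].
#' @export
simulate_ehr <- function(config = synth_config(), seed = 1L) {
  generate_outcomes(generate_population(config, seed), seed)
}

#' True latent covariate values at a landmark age
#'
#' The generator's error-free standardized marker values and carry-forward
#' flags at age `s`, for patients whose latent path is defined there
#' (i.e. everyone; eligibility is the caller's concern).  Used to test
#' stage-2 parameter recovery with the measurement-error-free covariates.
#'
#' @param pop A `synth_ehr` list.
#' @param s Landmark age in years.
#' @return A `data.table` with columns `patient_id`, `sex`, the four latent
#'   `z_*` values at `s`, and `diabetes`/`bp_med` flags at `s`.
#' @export
true_current_values <- function(pop, s) {
  config <- pop$config
  tr <- pop$truth
  bp <- as.numeric(s >= tr$bp_med_age)
  out <- data.table(patient_id = tr$patient_id, sex = tr$sex)
  for (k in MARKERS) {
    z <- config$true_beta0[[k]] + config$true_beta1[[k]] * (s - 30) +
      tr[[paste0("b_", k)]] +
      if (k == "sbp") config$bp_med_effect_on_sbp * bp else 0
    out[, (paste0("z_", k)) := z]
  }
  out[, `:=`(diabetes = as.numeric(s >= tr$diabetes_age), bp_med = bp)]
  out[]
}

#' Write the synthetic tables as delimited text
#'
#' @param pop A `synth_ehr` list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synth_ehr <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(registry = file.path(dir, "registry.csv"),
             measurements = file.path(dir, "measurements.csv"))
  data.table::fwrite(pop$registry, paths[["registry"]])
  data.table::fwrite(pop$measurements, paths[["measurements"]])
  invisible(paths)
}

#' Read registry and measurement tables written by [write_synth_ehr()]
#'
#' @param dir Directory containing `registry.csv` and `measurements.csv`.
#' @return A list with `registry` and `measurements` data.tables (dates
#'   parsed, keyed by patient).
#' @export
read_ehr_tables <- function(dir) {
  registry <- data.table::fread(file.path(dir, "registry.csv"))
  date_cols <- grep("_date$|^birth_date$", names(registry), value = TRUE)
  registry[, (date_cols) := lapply(.SD, as.Date), .SDcols = date_cols]
  setkey(registry, patient_id)
  measurements <- data.table::fread(file.path(dir, "measurements.csv"))
  if ("date" %in% names(measurements))
    measurements[, date := as.Date(date)]
  list(registry = registry, measurements = measurements)
}
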
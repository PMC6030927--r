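# Orchestration: the two-stage engine (fit on one dataset, predict for new
# patients), 10-fold cross-validation split by practice, and the end-to-end
# pipeline with plain-text artifacts.

#' Fit the full two-stage model on one dataset
#'
#' Builds the cohort (entry/exit rules, plausibility filters,
#' standardization), constructs every landmark dataset, fits the stage-1
#' multivariate mixed models per landmark age and sex where a variant needs
#' them, and fits the stage-2 super-landmark Cox model per variant.
#'
#' @param registry,measurements Raw registry and measurement tables.
#' @param landmarks Landmark age grid (default 40, 45, ..., 85).
#' @param variants Character vector of stage-2 variants (see
#'   [make_covariates()]).
#' @param control Stage-1 [mlmm_control()].
#' @param std_params Optional frozen [fit_standardization()] parameters
#'   (used by cross-validation to standardize held-out data with
#'   training-fold parameters); default fits them on this data.
#' @param study_start,study_end Study window dates.
#' @param horizon Prediction horizon in years.
#' @return A list of class `two_stage_model`: `std_params`, `stage1`
#'   (per landmark age, lists with `male`/`female` fits), `cox` (per
#'   variant), `landmark_data`, `flow`, `train_patient_ids`, settings.
#' @export
fit_two_stage <- function(registry, measurements,
                          landmarks = seq(40, 85, by = 5),
                          variants = c("basic", "current_values"),
                          control = mlmm_control(),
                          std_params = NULL,
                          study_start = "1997-01-01",
                          study_end = "2016-01-18",
                          horizon = 10) {
  cohort <- build_cohort(registry, measurements, study_start, study_end)
  if (!is.null(std_params)) {
    cohort$std_params <- std_params
    cohort$measurements <- standardize(
      apply_plausibility_filters(measurements)$measurements[
        patient_id %in% cohort$registry$patient_id],
      std_params, cohort$registry)
  }
  lds <- lapply(landmarks, build_landmark_dataset, cohort = cohort,
                grid = landmarks, horizon = horizon)
  names(lds) <- as.character(landmarks)

  need_stage1 <- any(variants %in% c("current_values", "age_interactions"))
  stage1 <- NULL
  if (need_stage1) {
    stage1 <- lapply(lds, function(ld) {
      fits <- lapply(c(male = "male", female = "female"), function(sx) {
        if (!any(ld$info$sex == sx)) return(NULL)
        tryCatch(fit_mlmm(ld, sx, control), error = function(e) NULL)
      })
      fits
    })
  }

  cox_fits <- list()
  cov_tables <- list()
  for (v in variants) {
    tabs <- lapply(seq_along(lds), function(i) {
      make_covariates(lds[[i]],
                      stage1 = if (is.null(stage1)) NULL else stage1[[i]],
                      variant = v)
    })
    stacked <- stack_landmarks(tabs)
    cox_fits[[v]] <- fit_cox(stacked)
    cov_tables[[v]] <- stacked
  }

  structure(list(std_params = cohort$std_params, stage1 = stage1,
                 cox = cox_fits, stacked = cov_tables,
                 landmark_data = lds, flow = cohort$flow,
                 removed = cohort$removed,
                 train_patient_ids = cohort$registry$patient_id,
                 landmarks = landmarks, variants = variants,
                 control = control, horizon = horizon,
                 study_start = study_start, study_end = study_end),
            class = "two_stage_model")
}

#' Predict 10-year risk for new patients from a fitted two-stage model
#'
#' Held-out patients are run through the same cohort rules, standardized
#' with the model's (training) parameters, and receive out-of-sample
#' empirical-Bayes BLUPs from the training stage-1 fits applied to their own
#' histories, then risks from the training Cox fit.
#'
#' @param model A [fit_two_stage()] object.
#' @param registry,measurements Tables for the new patients.
#' @return Named list (per variant) of prediction `data.table`s with
#'   `patient_id`, `lm_age`, `sex`, `lp`, `risk10`, `follow_time`, `event`.
#' @export
predict_two_stage <- function(model, registry, measurements) {
  cohort <- build_cohort2(registry, measurements, model$std_params,
                          model$study_start, model$study_end)
  lds <- lapply(model$landmarks, build_landmark_dataset, cohort = cohort,
                grid = model$landmarks, horizon = model$horizon)
  out <- list()
  for (v in model$variants) {
    tabs <- lapply(seq_along(lds), function(i) {
      make_covariates(lds[[i]],
                      stage1 = if (is.null(model$stage1)) NULL
                               else model$stage1[[i]],
                      variant = v)
    })
    stacked <- stack_landmarks(tabs)
    if (nrow(stacked) == 0) {
      out[[v]] <- data.table()
      next
    }
    pr <- predict_10y_risk(model$cox[[v]], stacked, model$horizon)
    pr[, `:=`(follow_time = stacked$follow_time, event = stacked$event)]
    out[[v]] <- pr
  }
  out
}

# cohort build with frozen standardization parameters
build_cohort2 <- function(registry, measurements, std_params,
                          study_start, study_end) {
  reg <- compute_study_window(registry, study_start, study_end)
  filt <- apply_plausibility_filters(measurements)
  meas <- filt$measurements
  keep <- reg[excluded == FALSE]
  win <- keep[, .(patient_id, entry_age, exit_age)]
  m <- win[meas, on = "patient_id", nomatch = NULL]
  qual <- unique(m[age >= entry_age & age <= exit_age, patient_id])
  study <- keep[patient_id %in% qual]
  meas <- meas[patient_id %in% study$patient_id]
  meas <- standardize(meas, std_params, study)
  setkey(study, patient_id)
  list(registry = study, measurements = meas, std_params = std_params,
       flow = list(study_sample = nrow(study)), removed = filt$removed)
}

#' Cross-validation split by general practice
#'
#' Practices are partitioned into `k` groups (whole practices are never
#' split).  For each fold, standardization, stage-1 and stage-2 models are
#' fitted on the training practices only; held-out patients receive
#' out-of-sample BLUPs from the training stage-1 parameters applied to
#' their own histories and risks from the training Cox fit.  Metrics are
#' pooled over all held-out predictions.
#'
#' @inheritParams fit_two_stage
#' @param k Number of folds; must not exceed the number of practices.
#' @param n_boot Bootstrap replicates for CIs in the pooled reports.
#' @param seed Seed for fold assignment and bootstrap.
#' @return A list of class `cv_result`: `predictions` (per variant, pooled),
#'   `reports` (per variant [validate_predictions()]), `comparison`
#'   (vs `"basic"` when present), `folds`, `leakage_ok`, `k`.
#' @export
cross_validate <- function(registry, measurements, k = 10,
                           landmarks = seq(40, 85, by = 5),
                           variants = c("basic", "current_values"),
                           control = mlmm_control(), n_boot = 200,
                           study_start = "1997-01-01",
                           study_end = "2016-01-18",
                           horizon = 10, seed = 1L) {
  registry <- as.data.table(registry)
  measurements <- as.data.table(measurements)
  practices <- sort(unique(registry$practice_id))
  if (k > length(practices))
    stop("k = ", k, " exceeds the number of practices (", length(practices), ")")
  set.seed(seed)
  fold_of <- setNames(rep(seq_len(k), length.out = length(practices))[
    sample(length(practices))], practices)
  folds <- data.table(practice_id = as.integer(names(fold_of)),
                      fold = as.integer(fold_of))

  acc <- lapply(setNames(nm = variants), function(v) list())
  leakage_ok <- TRUE
  for (f in seq_len(k)) {
    test_pr <- folds[fold == f, practice_id]
    train_reg <- registry[!practice_id %in% test_pr]
    test_reg <- registry[practice_id %in% test_pr]
    train_meas <- measurements[patient_id %in% train_reg$patient_id]
    test_meas <- measurements[patient_id %in% test_reg$patient_id]
    model <- fit_two_stage(train_reg, train_meas, landmarks, variants,
                           control, std_params = NULL,
                           study_start, study_end, horizon)
    if (length(intersect(test_reg$patient_id, model$train_patient_ids)))
      leakage_ok <- FALSE
    preds <- predict_two_stage(model, test_reg, test_meas)
    for (v in variants) {
      if (nrow(preds[[v]]) == 0) next
      preds[[v]][, fold := f]
      acc[[v]][[length(acc[[v]]) + 1L]] <- preds[[v]]
    }
  }
  pooled <- lapply(acc, function(x)
    if (length(x)) rbindlist(x) else data.table())
  reports <- lapply(pooled, function(tbl) {
    if (nrow(tbl) == 0) return(NULL)
    validate_predictions(tbl, n_boot = n_boot, horizon = horizon,
                         seed = seed)
  })
  comparison <- NULL
  if ("basic" %in% variants && length(variants) > 1) {
    comparison <- compare_models(pooled, reference = "basic",
                                 n_boot = n_boot, seed = seed)
  }
  structure(list(predictions = pooled, reports = reports,
                 comparison = comparison, folds = folds,
                 leakage_ok = leakage_ok, k = k, variants = variants),
            class = "cv_result")
}

#' Pipeline configuration
#'
#' @param synth A [synth_config()] for the simulated extract (ignored when
#'   the pipeline is pointed at existing tables).
#' @param landmarks Landmark age grid.
#' @param variants Stage-2 variants to fit and validate.
#' @param cv_k Cross-validation folds (split by practice).
#' @param n_boot Bootstrap replicates for confidence intervals.
#' @param lookback,visit_rate_adjust Stage-1 options (see [mlmm_control()]).
#' @param horizon Prediction horizon in years.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            landmarks = seq(40, 85, by = 5),
                            variants = c("basic", "current_values"),
                            cv_k = 10, n_boot = 200,
                            lookback = Inf, visit_rate_adjust = FALSE,
                            horizon = 10) {
  stopifnot(all(diff(landmarks) > 0))
  structure(list(synth = synth, landmarks = landmarks, variants = variants,
                 cv_k = cv_k, n_boot = n_boot, lookback = lookback,
                 visit_rate_adjust = visit_rate_adjust, horizon = horizon),
            class = "pipeline_config")
}

# small deterministic polynomial hash of a deparsed object, for artifact
# stamps (stays within 31 bits so no integer overflow)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline on synthetic data
#'
#' simulate, build the cohort, cross-validate all variants, fit the apparent
#' (full-data) models, and write plain-text artifacts (tables as CSV,
#' reports and fitted parameters as JSON) stamped with the configuration
#' hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Master seed for every source of randomness.
#' @return Invisibly, a list with the simulated data, the apparent
#'   [fit_two_stage()] model, the [cross_validate()] result, the incidence
#'   summary and the log.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  log <- list(config_hash = config_hash(unclass(config)), seed = seed)
  ehr <- simulate_ehr(config$synth, seed)
  control <- mlmm_control(lookback = config$lookback,
                          visit_rate_covariate = config$visit_rate_adjust)
  cohort <- build_cohort(ehr$registry, ehr$measurements)
  log$flow <- cohort$flow
  incidence <- incidence_summary(cohort$registry)

  model <- fit_two_stage(ehr$registry, ehr$measurements,
                         landmarks = config$landmarks,
                         variants = config$variants, control = control,
                         horizon = config$horizon)
  log$stage1_converged <- if (is.null(model$stage1)) NA else
    vapply(model$stage1, function(x)
      all(vapply(Filter(Negate(is.null), x), `[[`, logical(1), "converged")),
      logical(1))
  cv <- cross_validate(ehr$registry, ehr$measurements, k = config$cv_k,
                       landmarks = config$landmarks,
                       variants = config$variants, control = control,
                       n_boot = config$n_boot, horizon = config$horizon,
                       seed = seed)
  log$leakage_ok <- cv$leakage_ok
  log$runtime_seconds <- proc.time()[["elapsed"]] - t0

  result <- list(ehr = ehr, cohort = cohort, incidence = incidence,
                 model = model, cv = cv, log = log)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  invisible(result)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_synth_ehr(result$ehr, out_dir)
  data.table::fwrite(result$incidence, file.path(out_dir, "incidence.csv"))
  jsonlite::write_json(result$log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  # stage-1 parameters per landmark age and sex
  if (!is.null(result$model$stage1)) {
    st1 <- lapply(result$model$stage1, function(x)
      lapply(Filter(Negate(is.null), x), function(f)
        list(beta = as.list(f$beta), G = f$G, sigma2 = as.list(f$sigma2),
             logLik = f$logLik, converged = f$converged,
             n_patients = f$n_patients, n_obs = f$n_obs)))
    jsonlite::write_json(st1, file.path(out_dir, "stage1_params.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  for (v in names(result$model$cox)) {
    fit <- result$model$cox[[v]]
    cf <- data.table(term = names(fit$theta), coef = as.numeric(fit$theta),
                     se_model = sqrt(diag(fit$vcov_model)),
                     se_robust = sqrt(diag(fit$vcov_robust)))
    data.table::fwrite(cf, file.path(out_dir, paste0("cox_", v, ".csv")))
    data.table::fwrite(fit$breslow,
                       file.path(out_dir, paste0("breslow_", v, ".csv")))
  }
  for (v in names(result$cv$predictions)) {
    tbl <- result$cv$predictions[[v]]
    if (nrow(tbl))
      data.table::fwrite(tbl, file.path(out_dir,
                                        paste0("cv_predictions_", v, ".csv")))
  }
  rep_json <- lapply(result$cv$reports, function(r) {
    if (is.null(r)) return(NULL)
    list(brier = r$brier, brier_ci = r$brier_ci,
         brier_complete_case = r$brier_complete_case,
         cindex = r$cindex, cindex_ci = r$cindex_ci,
         cindex_by_landmark_age = r$cindex_by_landmark_age,
         calibration = r$calibration, n = r$n, n_events = r$n_events)
  })
  jsonlite::write_json(rep_json, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")
  if (!is.null(result$cv$comparison))
    data.table::fwrite(result$cv$comparison,
                       file.path(out_dir, "model_comparison.csv"))
  invisible(out_dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; keys under
#' `synth:` are passed to [synth_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(synth_args$true_G))
    synth_args$true_G <- matrix(unlist(synth_args$true_G), 4, 4,
                                dimnames = list(MARKERS, MARKERS))
  for (nm in c("visit_rates", "true_beta0", "true_beta1", "true_sigma2",
               "true_log_hazard_ratios"))
    if (!is.null(synth_args[[nm]])) synth_args[[nm]] <- unlist(synth_args[[nm]])
  synth <- do.call(synth_config, synth_args)
  args <- y[setdiff(names(y), "synth")]
  args$synth <- synth
  do.call(pipeline_config, args)
}
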
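# Censoring-aware validation of 10-year risk predictions: Brier score
# (IPCW and complete-case), Harrell C-index with landmark-stacking pair
# rules, calibration by decile of predicted risk, patient-clustered
# bootstrap confidence intervals, 10-fold cross-validation split by
# practice, and between-model comparison.

# Kaplan-Meier of the censoring distribution; returns a function giving the
# left-continuous survival G(t-) at arbitrary times
censoring_km <- function(time, event) {
  sf <- survfit(Surv(time, 1 - event) ~ 1)
  function(tt) {
    idx <- findInterval(tt, sf$time, left.open = TRUE)  # strictly before tt
    c(1, sf$surv)[idx + 1]
  }
}

#' Brier score for 10-year risk predictions under censoring
#'
#' Mean squared difference between the predicted risk and the observed
#' 10-year outcome.  In `"ipcw"` mode (default) subjects are reweighted by
#' the inverse Kaplan-Meier estimate of the censoring distribution
#' (Graf-style): events before the horizon get weight `1/G(T-)`, subjects
#' followed to the horizon get `1/G(horizon-)`, and subjects censored early
#' get weight 0; the sum is divided by the total number of subjects.  In
#' `"complete_case"` mode the plain mean over subjects whose horizon status
#' is known is returned; the two coincide when no censoring occurs before
#' the horizon.
#'
#' @param pred Predicted risks in \[0, 1\].
#' @param time,event Follow-up time (years since landmark) and event
#'   indicator.
#' @param horizon Horizon in years (default 10).
#' @param mode `"ipcw"` or `"complete_case"`.
#' @return The Brier score (scalar).
#' @export
brier_score <- function(pred, time, event, horizon = 10,
                        mode = c("ipcw", "complete_case")) {
  mode <- match.arg(mode)
  stopifnot(length(pred) == length(time), length(time) == length(event))
  if (any(pred < 0 | pred > 1)) stop("predictions must lie in [0, 1]")
  is_event <- event == 1 & time <= horizon
  is_surv <- time >= horizon
  if (mode == "complete_case") {
    known <- is_event | is_surv
    if (!any(known)) stop("no subject with known horizon status")
    outcome <- as.numeric(is_event[known])
    return(mean((outcome - pred[known])^2))
  }
  G <- censoring_km(time, event)
  g_h <- G(horizon)
  if (g_h <= 0) stop("censoring survival is 0 at the horizon; IPCW impossible")
  w <- numeric(length(pred))
  w[is_event] <- 1 / G(time[is_event])
  w[!is_event & is_surv] <- 1 / g_h
  outcome <- as.numeric(is_event)
  sum(w * (outcome - pred)^2) / length(pred)
}

#' Harrell C-index over pairs of different individuals
#'
#' Concordance of predicted risk scores with censored 10-year outcomes.
#' A pair is comparable when the smaller follow-up time is an event time and
#' the ordering is determinable; score ties count 1/2.  With stacked
#' landmark rows, pairs sharing a `patient_id` are excluded, and in
#' age-adjusted mode (`group` supplied, e.g. the landmark age) only
#' within-group pairs are compared.
#'
#' @param score Predicted risk or linear predictor (any monotone equivalent).
#' @param time,event Follow-up time and event indicator.
#' @param patient_id Optional cluster labels; same-cluster pairs are skipped.
#' @param group Optional grouping; only within-group pairs are compared.
#' @return The C-index, with attributes `concordant` and `comparable`.
#' @export
harrell_cindex <- function(score, time, event, patient_id = NULL,
                           group = NULL) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  id <- if (is.null(patient_id)) integer(n) else as.integer(factor(patient_id))
  gr <- if (is.null(group)) integer(n) else as.integer(factor(group))
  r <- cindex_pairs_cpp(as.numeric(score), as.numeric(time),
                        as.integer(event), id, gr,
                        !is.null(patient_id), !is.null(group))
  if (r$comparable == 0) stop("no comparable pairs")
  structure(r$concordant / r$comparable,
            concordant = r$concordant, comparable = r$comparable)
}

#' Calibration by decile of predicted risk
#'
#' Bins rows by deciles of the predicted risk (empirical quantiles; bins
#' that collapse under ties are merged with a warning) and compares, per
#' bin, the mean predicted risk with the observed risk
#' `1 - KM survival(horizon)` within the bin.
#'
#' @inheritParams brier_score
#' @param n_bins Number of quantile bins (default 10).
#' @return A `data.table`: `bin`, `n`, `n_events`, `mean_pred`, `obs_risk`.
#' @export
calibration_deciles <- function(pred, time, event, horizon = 10,
                                n_bins = 10) {
  if (length(pred) < n_bins) stop("need at least n_bins rows")
  qs <- quantile(pred, probs = seq(0, 1, length.out = n_bins + 1),
                 names = FALSE)
  br <- unique(qs)
  if (length(br) < 2) br <- c(min(pred) - 1e-12, max(pred) + 1e-12)
  if (length(br) < n_bins + 1)
    warning("tied predictions: ", n_bins + 1 - length(br),
            " bin boundary(ies) merged")
  bin <- cut(pred, breaks = br, include.lowest = TRUE, labels = FALSE)
  dt <- data.table(bin = bin, pred = pred, time = time, event = event)
  dt[, {
    sf <- survfit(Surv(time, event) ~ 1)
    idx <- findInterval(horizon, sf$time)
    s_h <- if (idx == 0) 1 else sf$surv[idx]
    .(n = .N, n_events = sum(event), mean_pred = mean(pred),
      obs_risk = 1 - s_h)
  }, by = bin][order(bin)]
}

# percentile bootstrap CI of a statistic computed on a prediction table,
# resampling whole patients (stacked rows move together; resampled copies
# of a patient are relabelled as distinct clusters)
cluster_boot_ci <- function(tbl, stat_fn, n_boot = 200, conf = 0.95,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(tbl$patient_id)
  split_idx <- split(seq_len(nrow(tbl)), match(tbl$patient_id, ids))
  stats <- vapply(seq_len(n_boot), function(b) {
    draw <- sample.int(length(ids), replace = TRUE)
    idx <- unlist(split_idx[draw], use.names = FALSE)
    reps <- vapply(split_idx[draw], length, integer(1))
    bt <- tbl[idx]
    bt[, patient_id := rep(seq_along(draw), reps)]
    tryCatch(stat_fn(bt), error = function(e) NA_real_)
  }, numeric(1))
  a <- (1 - conf) / 2
  quantile(stats, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}

#' Validation report for a table of predictions
#'
#' Computes the Brier score (IPCW and complete-case), the overall C-index
#' (pairs of different individuals), the age-adjusted C-index (within each
#' landmark age), and the calibration decile table, with patient-clustered
#' percentile-bootstrap confidence intervals for Brier and overall C-index.
#'
#' @param pred_tbl `data.table` with columns `patient_id`, `lm_age`,
#'   `risk10`, `follow_time`, `event`.
#' @param n_boot Bootstrap replicates for the CIs (0 skips CIs).
#' @param horizon Horizon in years.
#' @param seed Seed for the bootstrap.
#' @return A list of class `validation_report`.
#' @export
validate_predictions <- function(pred_tbl, n_boot = 200, horizon = 10,
                                 seed = NULL) {
  tbl <- as.data.table(pred_tbl)
  br <- brier_score(tbl$risk10, tbl$follow_time, tbl$event, horizon)
  br_cc <- brier_score(tbl$risk10, tbl$follow_time, tbl$event, horizon,
                       mode = "complete_case")
  ci <- as.numeric(harrell_cindex(tbl$risk10, tbl$follow_time, tbl$event,
                                  patient_id = tbl$patient_id))
  by_s <- tbl[, .(cindex = tryCatch(as.numeric(
    harrell_cindex(risk10, follow_time, event)), error = function(e) NA_real_),
    n = .N, n_events = sum(event)), by = lm_age][order(lm_age)]
  calib <- calibration_deciles(tbl$risk10, tbl$follow_time, tbl$event,
                               horizon)
  brier_ci <- cindex_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    brier_ci <- cluster_boot_ci(tbl, function(bt)
      brier_score(bt$risk10, bt$follow_time, bt$event, horizon),
      n_boot, seed = seed)
    cindex_ci <- cluster_boot_ci(tbl, function(bt)
      as.numeric(harrell_cindex(bt$risk10, bt$follow_time, bt$event,
                                patient_id = bt$patient_id)),
      n_boot, seed = seed)
  }
  structure(list(brier = br, brier_ci = brier_ci, brier_complete_case = br_cc,
                 cindex = ci, cindex_ci = cindex_ci,
                 cindex_by_landmark_age = by_s, calibration = calib,
                 n = nrow(tbl), n_events = sum(tbl$event),
                 n_patients = length(unique(tbl$patient_id))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (", x$n, "rows,", x$n_events, "events,",
      x$n_patients, "patients )\n")
  cat(sprintf("  Brier (IPCW): %.4f  [%.4f, %.4f]\n",
              x$brier, x$brier_ci[1], x$brier_ci[2]))
  cat(sprintf("  Brier (complete case): %.4f\n", x$brier_complete_case))
  cat(sprintf("  C-index: %.4f  [%.4f, %.4f]\n",
              x$cindex, x$cindex_ci[1], x$cindex_ci[2]))
  invisible(x)
}

#' Compare model variants on pooled cross-validated predictions
#'
#' Differences in C-index and Brier score of each variant against a
#' reference, with patient-clustered percentile-bootstrap confidence
#' intervals.  Comparisons use the common rows (patient x landmark age) of
#' the two prediction tables, so restricted-sample variants are compared on
#' the restricted rows.
#'
#' @param pred_tbls Named list of prediction tables (see
#'   [validate_predictions()]).
#' @param reference Name of the referent variant (default `"basic"`).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for the bootstrap.
#' @return A `data.table`: variant, `delta_cindex` (+CI), `delta_brier`
#'   (+CI), `n_common` rows.
#' @export
compare_models <- function(pred_tbls, reference = "basic", n_boot = 200,
                           seed = NULL) {
  stopifnot(reference %in% names(pred_tbls))
  ref <- as.data.table(pred_tbls[[reference]])
  out <- list()
  for (nm in names(pred_tbls)) {
    cmp <- as.data.table(pred_tbls[[nm]])
    j <- merge(ref[, .(patient_id, lm_age, follow_time, event,
                       risk_ref = risk10)],
               cmp[, .(patient_id, lm_age, risk_cmp = risk10)],
               by = c("patient_id", "lm_age"))
    if (nrow(j) == 0) stop("no common rows between '", nm,
                           "' and the reference")
    dstat <- function(bt) {
      as.numeric(harrell_cindex(bt$risk_cmp, bt$follow_time, bt$event,
                                patient_id = bt$patient_id)) -
        as.numeric(harrell_cindex(bt$risk_ref, bt$follow_time, bt$event,
                                  patient_id = bt$patient_id))
    }
    bstat <- function(bt) {
      brier_score(bt$risk_cmp, bt$follow_time, bt$event) -
        brier_score(bt$risk_ref, bt$follow_time, bt$event)
    }
    dc <- dstat(j)
    db <- bstat(j)
    dc_ci <- db_ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      dc_ci <- cluster_boot_ci(j, dstat, n_boot, seed = seed)
      db_ci <- cluster_boot_ci(j, bstat, n_boot, seed = seed)
    }
    out[[nm]] <- data.table(variant = nm, delta_cindex = dc,
                            delta_cindex_lo = dc_ci[1],
                            delta_cindex_hi = dc_ci[2],
                            delta_brier = db,
                            delta_brier_lo = db_ci[1],
                            delta_brier_hi = db_ci[2],
                            n_common = nrow(j))
  }
  rbindlist(out)
}
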
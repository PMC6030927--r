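# Stage 2: stack the landmark datasets, fit a sex-stratified Cox model on
# time since landmark age with patient-clustered robust standard errors,
# estimate the Breslow baseline cumulative hazard per stratum, and predict
# 10-year risk.

COX_VARIANTS <- c("basic", "current_values", "age_interactions",
                  "last_observed", "cumulative_mean")

# landmark age is centered at 60 and scaled by 10 for optimizer
# conditioning; coefficients are reported on this scale
lm_age_scaled <- function(s) (s - 60) / 10

#' Build the stage-2 covariate table for one landmark age
#'
#' All variants share landmark-age terms (centered and scaled:
#' `age_c = (s - 60)/10`, `age_c2 = age_c^2`) and the carry-forward diabetes
#' and BP-treatment flags at `s`.  `current_values` adds the four stage-1
#' estimated current risk-factor values; `last_observed` / `cumulative_mean`
#' substitute those comparator summaries (possibly `NA`, resolved at
#' stacking); `age_interactions` adds the product of `age_c` with each of
#' the six risk factors (the two flags and four markers).
#'
#' @param ld A [build_landmark_dataset()].
#' @param stage1 For the `current_values` and `age_interactions` variants, a
#'   list of two [fit_mlmm()] objects named `male` and `female` for this
#'   landmark age.
#' @param variant One of `r paste0('"', COX_VARIANTS, '"', collapse = ", ")`.
#' @return A `data.table`, one row per eligible patient, carrying
#'   `follow_time` and `event` along with the covariates; the covariate
#'   column names are in `attr(, "cov_names")` and the variant in
#'   `attr(, "variant")`.
#' @export
make_covariates <- function(ld, stage1 = NULL, variant = "current_values") {
  if (!variant %in% COX_VARIANTS)
    stop("unknown variant '", variant, "'")
  base <- copy(ld$info)
  base[, `:=`(age_c = lm_age_scaled(lm_age), age_c2 = lm_age_scaled(lm_age)^2)]
  covs <- c("age_c", "age_c2", "diabetes", "bp_med")

  add_markers <- function(tbl, prefix) {
    cns <- paste0(prefix, MARKERS)
    if (is.null(tbl) || nrow(tbl) == 0L) {
      for (cn in cns) base[, (cn) := NA_real_]
      return(cns)
    }
    for (cn in cns) {
      base[tbl, on = "patient_id", (cn) := get(paste0("i.", cn))]
      if (!cn %in% names(base)) base[, (cn) := NA_real_]
    }
    cns
  }

  if (variant %in% c("current_values", "age_interactions")) {
    if (is.null(stage1))
      stop("stage-1 fits required for variant '", variant, "'")
    cv <- rbindlist(lapply(c("male", "female"), function(sx) {
      if (is.null(stage1[[sx]])) return(NULL)
      estimate_current_values(stage1[[sx]], ld)[
        , c("patient_id", paste0("cur_", MARKERS)), with = FALSE]
    }))
    covs <- c(covs, add_markers(cv, "cur_"))
  } else if (variant == "last_observed") {
    lo <- last_observed(ld)
    setnames(lo, MARKERS, paste0("lo_", MARKERS))
    covs <- c(covs, add_markers(lo, "lo_"))
  } else if (variant == "cumulative_mean") {
    cm <- cumulative_mean(ld)
    setnames(cm, MARKERS, paste0("cm_", MARKERS))
    covs <- c(covs, add_markers(cm, "cm_"))
  }

  if (variant == "age_interactions") {
    for (k in c("diabetes", "bp_med", paste0("cur_", MARKERS))) {
      cn <- paste0(k, "_x_age")
      base[, (cn) := get(k) * age_c]
      covs <- c(covs, cn)
    }
  }
  setattr(base, "cov_names", covs)
  setattr(base, "variant", variant)
  base[]
}

#' Stack per-landmark covariate tables into a super-landmark dataset
#'
#' Rows are concatenated over landmark ages, so a patient eligible at k
#' landmark ages contributes k rows.  For the restricted-sample variants
#' (`last_observed`, `cumulative_mean`) rows with any missing covariate are
#' dropped and the count recorded in `attr(, "n_dropped")`.
#'
#' @param tables List of [make_covariates()] outputs (same variant/schema).
#' @return The stacked `data.table` with attributes `cov_names`, `variant`,
#'   `n_dropped`.
#' @export
stack_landmarks <- function(tables) {
  variant <- attr(tables[[1]], "variant")
  covs <- attr(tables[[1]], "cov_names")
  for (tb in tables)
    if (!identical(attr(tb, "variant"), variant) ||
        !identical(attr(tb, "cov_names"), covs))
      stop("covariate tables do not share a schema")
  stacked <- rbindlist(tables)
  if (anyDuplicated(stacked[, .(patient_id, lm_age)]))
    stop("duplicate (patient, landmark age) rows")
  n0 <- nrow(stacked)
  cc <- complete.cases(stacked[, covs, with = FALSE])
  stacked <- stacked[cc]
  setattr(stacked, "cov_names", covs)
  setattr(stacked, "variant", variant)
  setattr(stacked, "n_dropped", n0 - nrow(stacked))
  stacked[]
}

#' Fit the sex-stratified super-landmark Cox model
#'
#' Maximizes the stratified Cox partial likelihood (Breslow tie handling by
#' default) with time since landmark age as the time scale, computes the
#' patient-clustered sandwich covariance, and estimates the Breslow baseline
#' cumulative hazard per sex stratum from the uncentered linear predictor.
#'
#' @param stacked A [stack_landmarks()] table.
#' @param cluster Column to cluster robust standard errors on
#'   (default `"patient_id"`; `"practice_id"` is a supported alternative).
#' @param ties `"breslow"` (default) or `"efron"` for the partial
#'   likelihood; the baseline estimator is always Breslow.
#' @return An object of class `slm_cox`: `theta` (log hazard ratios),
#'   `vcov_model`, `vcov_robust`, `breslow` (per-sex step function of the
#'   cumulative baseline hazard), counts, and the fitted `coxph` object.
#' @export
fit_cox <- function(stacked, cluster = "patient_id", ties = "breslow") {
  covs <- attr(stacked, "cov_names")
  if (is.null(covs)) stop("stacked table lacks covariate metadata")
  dat <- as.data.table(stacked)
  if (any(dat$follow_time <= 0)) stop("nonpositive follow-up time")
  ev_by_sex <- dat[, sum(event), by = sex]
  if (any(ev_by_sex$V1 < 1) || nrow(ev_by_sex) == 0)
    stop("at least one event per sex stratum is required")
  const <- covs[vapply(covs, function(cn) {
    v <- dat[[cn]]
    all(v == v[1])
  }, logical(1))]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "))

  fml <- as.formula(paste("Surv(follow_time, event) ~",
                          paste(covs, collapse = " + "),
                          "+ strata(sex)"))
  cl <- dat[[cluster]]
  fit_warnings <- character()
  fit <- withCallingHandlers(
    coxph(fml, data = dat, ties = ties, cluster = cl,
          robust = TRUE, x = FALSE, y = FALSE),
    warning = function(w) {
      fit_warnings <<- c(fit_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(is.na(coef(fit))))
    stop("Cox fit produced NA coefficients (collinearity or separation)")
  # monotone-likelihood / iteration warnings are kept as a flag on the fit
  flagged <- any(grepl("infinite|did not converge", fit_warnings))
  theta <- coef(fit)
  X <- as.matrix(dat[, covs, with = FALSE])
  lp <- as.numeric(X %*% theta)
  breslow <- rbindlist(lapply(split(seq_len(nrow(dat)), dat$sex), function(idx) {
    breslow_cumhaz(dat$follow_time[idx], dat$event[idx], lp[idx])[
      , sex := dat$sex[idx[1]]]
  }))
  structure(list(theta = theta,
                 vcov_model = fit$naive.var %||% vcov(fit),
                 vcov_robust = fit$var,
                 breslow = breslow,
                 cov_names = covs,
                 variant = attr(stacked, "variant"),
                 ties = ties, cluster = cluster,
                 n = nrow(dat), n_events = sum(dat$event),
                 strata_levels = unique(dat$sex),
                 flagged = flagged, fit_warnings = fit_warnings,
                 coxph = fit),
            class = "slm_cox")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Breslow estimator of the cumulative baseline hazard on (0, horizon]:
# steps at distinct event times t_j of size d_j / sum_{time >= t_j} exp(lp)
breslow_cumhaz <- function(time, event, lp) {
  o <- order(time)
  time <- time[o]; event <- event[o]; elp <- exp(lp[o])
  # risk-set denominator: reverse cumulative sum of exp(lp)
  denom_all <- rev(cumsum(rev(elp)))
  et <- unique(time[event == 1])
  d <- vapply(et, function(tt) sum(event == 1 & time == tt), numeric(1))
  den <- vapply(et, function(tt) denom_all[match(TRUE, time >= tt)], numeric(1))
  data.table(time = et, hazard = d / den, cumhaz = cumsum(d / den))
}

#' Predict 10-year risk from a fitted super-landmark model
#'
#' `risk = 1 - exp(-Lambda0_sex(horizon) * exp(x' theta))` with the Breslow
#' baseline of the patient's sex stratum.
#'
#' @param fit An [fit_cox()] object.
#' @param newdata Covariate table (e.g. from [make_covariates()]); must
#'   contain the fit's covariate columns and `sex`.
#' @param horizon Prediction horizon in years (default 10).
#' @return A `data.table`: `patient_id`, `lm_age`, `sex`, `lp`, `risk10`.
#' @export
predict_10y_risk <- function(fit, newdata, horizon = 10) {
  dat <- as.data.table(newdata)
  miss_sex <- setdiff(unique(dat$sex), fit$strata_levels)
  if (length(miss_sex))
    stop("sex stratum absent from fit: ", paste(miss_sex, collapse = ", "))
  X <- as.matrix(dat[, fit$cov_names, with = FALSE])
  lp <- as.numeric(X %*% fit$theta)
  H <- vapply(dat$sex, function(sx) {
    b <- fit$breslow[sex == sx]
    if (nrow(b) == 0) return(0)
    idx <- findInterval(horizon, b$time)
    if (idx == 0) 0 else b$cumhaz[idx]
  }, numeric(1))
  risk <- ifelse(H == 0, 0, 1 - exp(-H * exp(lp)))
  out <- data.table(patient_id = dat$patient_id,
                    lm_age = if ("lm_age" %in% names(dat)) dat$lm_age else NA,
                    sex = dat$sex, lp = lp, risk10 = risk)
  out[]
}

#' @export
print.slm_cox <- function(x, ...) {
  cat("Super-landmark Cox model (variant:", x$variant, ")\n")
  cat("  rows:", x$n, " events:", x$n_events, "\n")
  se_m <- sqrt(diag(x$vcov_model))
  se_r <- sqrt(diag(x$vcov_robust))
  tab <- data.frame(coef = round(x$theta, 4), HR = round(exp(x$theta), 4),
                    se_model = round(se_m, 4), se_robust = round(se_r, 4))
  print(tab)
  invisible(x)
}
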
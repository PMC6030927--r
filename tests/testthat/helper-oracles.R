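# Independent oracles and fixture builders shared across the test files.
# Every oracle re-derives its quantity from first principles (enumeration,
# closed form, or direct conditioning) without touching the implementation
# path it checks.

library(data.table)

MK <- c("smoking", "sbp", "tchol", "hdlc")

# ---- conditional-MVN BLUP oracle -------------------------------------------
# Build the joint covariance of (b, y) and condition directly:
# b | y ~ mean G Z' (Z G Z' + R)^{-1} (y - X beta)
oracle_blup <- function(G, sigma2, beta, X, marker_idx, y) {
  n <- length(y)
  K <- nrow(G)
  Z <- matrix(0, n, K)
  for (r in seq_len(n)) Z[r, marker_idx[r]] <- 1
  Vy <- Z %*% G %*% t(Z) + diag(sigma2[marker_idx], n)
  Cby <- G %*% t(Z)
  as.numeric(Cby %*% solve(Vy, y - as.numeric(X %*% beta)))
}

# random PSD covariance with unit-scale variances
random_psd <- function(K, scale = 1) {
  A <- matrix(rnorm(K * K), K)
  S <- crossprod(A) / K
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d) * scale
  (S + t(S)) / 2
}

# hand-made mlmm_fit object with given parameters (bypasses fitting)
manual_mlmm_fit <- function(beta, G, sigma2, s = 60,
                            markers = rownames(G),
                            control = mlmm_control()) {
  structure(list(beta = beta, G = G, sigma2 = sigma2, logLik = NA_real_,
                 converged = TRUE, s = s, sex = "male", markers = markers,
                 inestimable = setdiff(MK, markers), dropped = character(),
                 control = control),
            class = "mlmm_fit")
}

# ---- direct simulation from the stage-1 measurement model ------------------
# y = beta0_k + beta1_k * t + gamma * bp * [k==sbp] + b_ik + eps; t in [-20,0]
simulate_mlmm_data <- function(n, beta0, beta1, gamma, G, sigma2,
                               m_per_marker = 4, s = 60, bp_frac = 0.3) {
  L <- t(chol(G + diag(1e-12, 4)))
  rows <- vector("list", n)
  info <- data.table(patient_id = seq_len(n), practice_id = 1L, sex = "male",
                     lm_age = s, diabetes = 0, bp_med = 0,
                     follow_time = 10, event = 0)
  bp_at_s <- numeric(n)
  bmat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    b <- as.numeric(L %*% rnorm(4))
    bmat[i, ] <- b
    bp_age <- if (runif(1) < bp_frac) runif(1, s - 15, s) else Inf
    bp_at_s[i] <- as.numeric(bp_age <= s)
    out <- list()
    for (j in seq_along(MK)) {
      k <- MK[j]
      m <- sample(m_per_marker[1]:max(m_per_marker), 1)
      tt <- sort(runif(m, -20, 0))
      bp <- as.numeric(s + tt >= bp_age)
      y <- beta0[j] + beta1[j] * tt + (k == "sbp") * gamma * bp + b[j] +
        rnorm(m, sd = sqrt(sigma2[j]))
      out[[k]] <- data.table(patient_id = i, marker = k, age = s + tt,
                             value_std = y, t_lm = tt, bp_med_at_meas = bp)
    }
    rows[[i]] <- rbindlist(out)
  }
  info[, bp_med := bp_at_s]
  hist <- rbindlist(rows)
  setkey(hist, patient_id, marker, age)
  ld <- structure(list(s = s, info = info, history = hist, horizon = 10),
                  class = "landmark_dataset")
  list(ld = ld, b = bmat)
}

# ---- brute-force Cox partial likelihood (Breslow ties) ---------------------
cox_partial_loglik <- function(theta, time, event, X, strata = NULL) {
  if (is.null(strata)) strata <- rep(1, length(time))
  lp <- as.numeric(X %*% theta)
  ll <- 0
  for (st in unique(strata)) {
    idx <- which(strata == st)
    for (tt in unique(time[idx][event[idx] == 1])) {
      d <- idx[time[idx] == tt & event[idx] == 1]
      risk <- idx[time[idx] >= tt]
      ll <- ll + sum(lp[d]) - length(d) * log(sum(exp(lp[risk])))
    }
  }
  ll
}

# hand enumeration of the Breslow baseline cumulative hazard steps
oracle_breslow <- function(theta, time, event, X) {
  lp <- as.numeric(X %*% theta)
  et <- sort(unique(time[event == 1]))
  steps <- vapply(et, function(tt) {
    sum(event == 1 & time == tt) / sum(exp(lp[time >= tt]))
  }, numeric(1))
  data.table(time = et, cumhaz = cumsum(steps))
}

# minimal stacked table with the attributes fit_cox() expects
mk_stacked <- function(dt, covs, variant = "basic") {
  dt <- as.data.table(dt)
  setattr(dt, "cov_names", covs)
  setattr(dt, "variant", variant)
  dt
}

# ---- pairwise C-index enumeration oracle -----------------------------------
oracle_cindex <- function(score, time, event, id = NULL, group = NULL) {
  n <- length(score)
  conc <- comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.null(id) && id[i] == id[j]) next
      if (!is.null(group) && group[i] != group[j]) next
      cas <- oth <- NA
      if (time[i] < time[j] && event[i] == 1) { cas <- i; oth <- j }
      if (time[j] < time[i] && event[j] == 1) { cas <- j; oth <- i }
      if (time[i] == time[j] && event[i] != event[j]) {
        cas <- if (event[i] == 1) i else j
        oth <- if (event[i] == 1) j else i
      }
      if (is.na(cas)) next
      comp <- comp + 1
      conc <- conc + (score[cas] > score[oth]) + 0.5 * (score[cas] == score[oth])
    }
  }
  conc / comp
}

# ---- IPCW Brier oracle with a hand-rolled censoring KM ---------------------
oracle_brier_ipcw <- function(pred, time, event, horizon = 10) {
  # KM of the censoring distribution (censoring = 1 - event)
  ut <- sort(unique(time))
  surv <- 1
  km_t <- km_s <- numeric(0)
  for (tt in ut) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 0)
    surv <- surv * (1 - d / at_risk)
    km_t <- c(km_t, tt)
    km_s <- c(km_s, surv)
  }
  Gminus <- function(tt) {   # left limit
    before <- km_t < tt
    if (!any(before)) 1 else km_s[max(which(before))]
  }
  tot <- 0
  for (i in seq_along(pred)) {
    if (event[i] == 1 && time[i] <= horizon) {
      tot <- tot + (1 - pred[i])^2 / Gminus(time[i])
    } else if (time[i] >= horizon) {
      tot <- tot + (0 - pred[i])^2 / Gminus(horizon)
    }
  }
  tot / length(pred)
}

# ---- tiny registry fixture builder -----------------------------------------
mk_patient <- function(patient_id = 1L, sex = "male",
                       birth = "1950-01-01", registration = "1990-01-01",
                       acu = "1995-01-01", amr = "1995-01-01",
                       transfer = NA, death = NA, cvd = NA,
                       diabetes = NA, bp_med = NA, statin = NA,
                       practice_id = 1L) {
  as_d <- function(x) if (length(x) == 1 && is.na(x)) as.Date(NA) else as.Date(x)
  data.table(patient_id = as.integer(patient_id), practice_id = practice_id,
             sex = sex, birth_date = as.Date(birth),
             registration_date = as.Date(registration),
             acceptable_computer_usage_date = as.Date(acu),
             acceptable_mortality_reporting_date = as.Date(amr),
             transfer_out_date = as_d(transfer), death_date = as_d(death),
             first_cvd_event_date = as_d(cvd),
             first_diabetes_date = as_d(diabetes),
             first_bp_med_date = as_d(bp_med),
             first_statin_date = as_d(statin))
}

# landmark dataset built directly from components (skips cohort rules)
mk_landmark_dataset <- function(info, history, s = 60, horizon = 10) {
  structure(list(s = s, info = as.data.table(info),
                 history = as.data.table(history), horizon = horizon),
            class = "landmark_dataset")
}
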
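# Stage 1: landmark-age- and sex-specific multivariate linear mixed model
# with correlated random intercepts for the four markers.
#
# Time origin is t = age - s (t <= 0), so the per-marker fixed intercept IS
# the error-free current value at the landmark age for a patient with average
# random effects, and the BLUP of the random intercept is the individual
# deviation.  Fixed effects: intercept and slope per marker, plus an
# indicator of blood-pressure-lowering treatment at measurement time acting
# on SBP rows only, plus (optionally) a per-marker annual visit rate in the
# 5 years before the landmark.  beta is profiled out by GLS so the optimizer
# works on the Cholesky factor of G (log-diagonal) and log residual
# variances only; the analytic gradient is computed in compiled code.

#' Stage-1 fitting options
#'
#' @param lookback Lookback window in years: only measurements with
#'   `age > s - lookback` enter the model (default `Inf`, i.e. the full
#'   history from age 30; the sensitivity value used in practice is 10).
#' @param visit_rate_covariate If `TRUE`, each marker's annual measurement
#'   rate in the 5 years before the landmark is added as a fixed covariate
#'   for that marker's rows (proxy for visit-intensity bias).
#' @param reml If `TRUE`, the REML criterion is maximized instead of plain
#'   ML (numeric gradient); default is ML.
#' @param max_iter,rel_tol,grad_tol BFGS iteration cap, relative
#'   log-likelihood tolerance and gradient-norm target.
#' @param n_starts Number of starting points (1 = moment-based only,
#'   2 adds a diagonal-G start to guard against local optima).
#' @param fix_G Optionally a fixed covariance matrix for the random
#'   intercepts (e.g. a zero matrix degenerates the model to per-marker
#'   least squares); when supplied only the residual variances are estimated.
#' @param slopes If `FALSE`, per-marker slopes on `t` are omitted.
#' @return A list of class `mlmm_control`.
#' @export
mlmm_control <- function(lookback = Inf, visit_rate_covariate = FALSE,
                         reml = FALSE, max_iter = 500L, rel_tol = 1e-8,
                         grad_tol = 1e-6, n_starts = 2L, fix_G = NULL,
                         slopes = TRUE) {
  stopifnot(lookback > 0, max_iter >= 1)
  structure(list(lookback = lookback,
                 visit_rate_covariate = visit_rate_covariate,
                 reml = reml, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, grad_tol = grad_tol,
                 n_starts = as.integer(n_starts), fix_G = fix_G,
                 slopes = slopes),
            class = "mlmm_control")
}

#' Annual measurement rate before a landmark age
#'
#' Count of measurement ages in `(max(s - window, 30), s]` divided by the
#' (possibly truncated) window length.
#'
#' @param ages Numeric vector of measurement ages for one patient/marker.
#' @param s Landmark age.
#' @param window Window length in years (default 5).
#' @return Rate per year.
#' @export
annual_visit_rate <- function(ages, s, window = 5) {
  lo <- max(s - window, 30)
  len <- s - lo
  if (len <= 0) return(0)
  sum(ages > lo & ages <= s) / len
}

# Assemble the per-stratum design.  Rows are history measurements of
# patients of the given sex, sorted by patient; patients with no in-window
# rows keep an empty block so the BLUP fall-back to the prior mean applies.
# Returns NULL columns dropped (zero-variance) with names recorded.
mlmm_design <- function(ld, sex, control, markers = NULL) {
  sel <- if (sex == "all") rep(TRUE, nrow(ld$info)) else ld$info[["sex"]] == sex
  info <- ld$info[sel]
  pts <- info$patient_id
  h <- ld$history[patient_id %in% pts]
  if (is.finite(control$lookback)) h <- h[t_lm > -control$lookback]
  # `markers` forces the marker universe (used when applying a fitted model
  # to new data whose observed marker set may be smaller)
  forced <- !is.null(markers)
  markers_present <- if (forced) markers else
    MARKERS[MARKERS %in% unique(h$marker)]
  inestimable <- setdiff(MARKERS, markers_present)
  h <- h[marker %in% markers_present]
  # order rows by patient; build offsets over ALL patients in the stratum
  setkey(h, patient_id, marker, age)
  idx <- match(h$patient_id, pts)
  o <- order(idx)
  h <- h[o]
  idx <- idx[o]
  cnt <- tabulate(idx, nbins = length(pts))
  pstart <- c(0L, cumsum(cnt))
  K <- length(markers_present)
  mk <- match(h$marker, markers_present) - 1L

  rates <- NULL
  if (control$visit_rate_covariate) {
    r <- h[, .(rate = annual_visit_rate(age, ld$s)), by = .(patient_id, marker)]
    rates <- dcast(r, patient_id ~ marker, value.var = "rate", fill = 0)
    for (k in setdiff(markers_present, names(rates))) rates[, (k) := 0]
  }

  cols <- list()
  for (j in seq_len(K)) {
    k <- markers_present[j]
    ind <- as.numeric(mk == j - 1L)
    cols[[paste0("mu_", k)]] <- ind
    if (control$slopes) cols[[paste0("slope_", k)]] <- ind * h$t_lm
  }
  if ("sbp" %in% markers_present)
    cols[["bp_med_sbp"]] <- as.numeric(h$marker == "sbp") * h$bp_med_at_meas
  if (control$visit_rate_covariate) {
    rmap <- rates[match(h$patient_id, rates$patient_id)]
    for (k in markers_present) {
      rv <- rmap[[k]]
      rv[is.na(rv)] <- 0
      cols[[paste0("rate_", k)]] <- as.numeric(h$marker == k) * rv
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(h), ncol = 0)
  colnames(X) <- names(cols)
  dropped <- character()
  if (!forced && ncol(X)) {
    keep <- apply(X, 2, function(z) any(z != 0))
    dropped <- colnames(X)[!keep]
    X <- X[, keep, drop = FALSE]
  }
  list(y = h$value_std, X = X, marker = mk, pstart = as.integer(pstart),
       patient_ids = pts, markers = markers_present,
       inestimable = inestimable, dropped = dropped, info = info,
       rates = rates, n_obs_rows = nrow(h))
}

theta_to_LS <- function(theta, K, fix_G) {
  nl <- K * (K + 1) / 2
  if (is.null(fix_G)) {
    L <- matrix(0, K, K)
    L[lower.tri(L, diag = TRUE)] <- theta[seq_len(nl)]
    diag(L) <- exp(diag(L))
    s2 <- exp(theta[nl + seq_len(K)])
  } else {
    L <- t(chol(fix_G + diag(1e-12, K)))  # tolerate PSD fix_G (incl. zero)
    if (all(fix_G == 0)) L <- matrix(0, K, K)
    s2 <- exp(theta)
  }
  list(L = L, s2 = s2)
}

#' Fit the stage-1 multivariate linear mixed model
#'
#' Maximizes the marginal (profile) log-likelihood
#' `sum_i log MVN(y_i; X_i beta, Z_i G Z_i' + R_i)` over the Cholesky factor
#' of the 4x4 random-intercept covariance `G` and the per-marker residual
#' variances, with the fixed effects profiled out by generalized least
#' squares.  Markers with no measurements in the stratum are reported as
#' inestimable rather than silently defaulted.
#'
#' @param ld A [build_landmark_dataset()] with standardized history.
#' @param sex `"male"` or `"female"` (models are fitted separately by sex).
#' @param control An [mlmm_control()].
#' @return An object of class `mlmm_fit`: named fixed effects `beta`,
#'   covariance `G`, residual variances `sigma2`, `logLik`, `converged`,
#'   `vcov_beta`, counts, the landmark age and sex, and the control used.
#' @export
fit_mlmm <- function(ld, sex, control = mlmm_control()) {
  d <- mlmm_design(ld, sex, control)
  if (length(d$patient_ids) == 0L)
    stop("no eligible patients in stratum (s = ", ld$s, ", ", sex, ")")
  if (d$n_obs_rows == 0L)
    stop("no measurements at all in stratum (s = ", ld$s, ", ", sex, ")")
  if (d$n_obs_rows <= ncol(d$X))
    stop("too few measurements to identify the fixed effects (s = ",
         ld$s, ", ", sex, ")")
  K <- length(d$markers)
  nl <- K * (K + 1) / 2
  fixG <- control$fix_G
  if (!is.null(fixG)) fixG <- fixG[d$markers, d$markers, drop = FALSE]

  # fn and gr share one likelihood evaluation per point (BFGS calls both)
  cache <- new.env(parent = emptyenv())
  eval_point <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    ls <- theta_to_LS(theta, K, fixG)
    res <- mlmm_nll_cpp(d$y, d$X, d$marker, d$pstart, ls$L, ls$s2,
                        !control$reml, control$reml)
    res$ls <- ls
    cache$theta <- theta
    cache$res <- res
    res
  }
  obj <- function(theta) {
    r <- eval_point(theta)
    if (!isTRUE(r$ok) || !is.finite(r$nll)) return(1e10)
    r$nll
  }
  grad <- function(theta) {
    r <- eval_point(theta)
    if (!isTRUE(r$ok)) return(rep(0, length(theta)))
    gs2 <- as.numeric(r$grad_sigma2) * r$ls$s2        # chain: log sigma2
    if (!is.null(fixG)) return(gs2)
    gL <- r$grad_L
    diag(gL) <- diag(gL) * diag(r$ls$L)               # chain: log diag(L)
    c(gL[lower.tri(gL, diag = TRUE)], gs2)
  }

  starts <- mlmm_starts(d, K, control)
  best <- NULL
  for (th0 in starts[seq_len(min(control$n_starts, length(starts)))]) {
    op <- tryCatch(
      optim(th0, obj, gr = if (control$reml) NULL else grad,
            method = "BFGS",
            control = list(maxit = control$max_iter,
                           reltol = control$rel_tol)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("stage-1 optimization failed for all starts")

  ls <- theta_to_LS(best$par, K, fixG)
  fin <- mlmm_nll_cpp(d$y, d$X, d$marker, d$pstart, ls$L, ls$s2,
                      !control$reml, control$reml)
  if (!isTRUE(fin$ok))
    stop("stage-1 likelihood is degenerate at the optimum (s = ",
         ld$s, ", ", sex, ")")
  gnorm <- if (control$reml) NA_real_ else sqrt(sum(grad(best$par)^2))
  converged <- best$convergence == 0 &&
    (is.na(gnorm) || gnorm < max(control$grad_tol, 1e-4 * abs(fin$nll)))
  beta <- as.numeric(fin$beta)
  names(beta) <- colnames(d$X)
  G <- ls$L %*% t(ls$L)
  dimnames(G) <- list(d$markers, d$markers)
  sigma2 <- setNames(as.numeric(ls$s2), d$markers)
  vb <- tryCatch(solve(fin$XtVX), error = function(e) NULL)
  if (!is.null(vb)) dimnames(vb) <- list(names(beta), names(beta))

  structure(list(beta = beta, G = G, sigma2 = sigma2,
                 logLik = -best$value, converged = converged,
                 grad_norm = gnorm,
                 n_patients = sum(diff(d$pstart) > 0),
                 n_obs = d$n_obs_rows,
                 s = ld$s, sex = sex, markers = d$markers,
                 inestimable = d$inestimable, dropped = d$dropped,
                 vcov_beta = vb, control = control),
            class = "mlmm_fit")
}

# moment-based and diagonal starting values on the theta scale
mlmm_starts <- function(d, K, control) {
  y <- d$y
  mk <- d$marker
  # per-marker OLS residual decomposition
  vtot <- sg <- s2 <- numeric(K)
  resid <- numeric(length(y))
  for (j in seq_len(K)) {
    idx <- which(mk == j - 1L)
    v <- y[idx]
    resid[idx] <- v - mean(v)
    vtot[j] <- max(var(v), 1e-4)
  }
  # between-patient component from per-patient residual means
  pid <- rep(seq_along(diff(d$pstart)), diff(d$pstart))
  dt <- data.table(p = pid, m = mk, r = resid)
  pm <- dt[, .(rm = mean(r), n = .N), by = .(p, m)]
  for (j in seq_len(K)) {
    rm <- pm[m == j - 1L & n >= 1, rm]
    sg[j] <- min(max(var(rm), 1e-4), 0.95 * vtot[j])
    if (is.na(sg[j])) sg[j] <- 0.5 * vtot[j]
    s2[j] <- max(vtot[j] - sg[j], 1e-4)
  }
  mk_moment <- function(Gd, s2d) {
    L <- t(chol(Gd + diag(1e-8, K)))
    th <- L
    diag(th) <- log(diag(L))
    c(th[lower.tri(th, diag = TRUE)], log(s2d))
  }
  if (!is.null(control$fix_G)) {
    return(list(log(pmax(vtot * 0.7, 1e-4)), log(pmax(vtot * 0.4, 1e-4))))
  }
  # moment start with pairwise covariances of patient means
  W <- dcast(pm, p ~ m, value.var = "rm")
  Gm <- diag(sg, K)
  if (ncol(W) > 2) {
    M <- as.matrix(W[, -1])
    Cm <- suppressWarnings(stats::cov(M, use = "pairwise.complete.obs"))
    Cm[is.na(Cm)] <- 0
    ev <- eigen((Cm + t(Cm)) / 2, symmetric = TRUE)
    Cm <- ev$vectors %*% diag(pmax(ev$values, 1e-4), K) %*% t(ev$vectors)
    diag(Cm) <- sg
    Gm <- (Cm + t(Cm)) / 2
    ev <- eigen(Gm, symmetric = TRUE)
    Gm <- ev$vectors %*% diag(pmax(ev$values, 1e-4), K) %*% t(ev$vectors)
  }
  list(mk_moment(Gm, s2), mk_moment(diag(0.5 * vtot, K), 0.5 * vtot))
}

#' Empirical-Bayes BLUP for one patient
#'
#' Posterior mean of the random intercepts given the patient's observed
#' history, `bhat = G Z' V^{-1} (y - X beta)`, and the implied current
#' risk-factor values at the landmark age,
#' `mu_k(s) = beta0_k + bhat_k + gamma 1[on BP med at s, k = sbp]`
#' (plus the visit-rate term when that covariate is in the model).  Works
#' for any subset of observed markers, including patients absent from the
#' fitting data; with no observations the BLUP is zero and the current value
#' is the fixed-effect (prior-mean) prediction.
#'
#' @param fit An [fit_mlmm()] object.
#' @param history `data.table` of the patient's measurements with columns
#'   `marker`, `t_lm` (age minus landmark age, <= 0), `value_std`,
#'   `bp_med_at_meas`.  May have zero rows.
#' @param bp_med_at_s 0/1 BP-treatment status at the landmark age.
#' @param ages Optional measurement ages (needed only when the fit includes
#'   the visit-rate covariate); defaults to `s + t_lm`.
#' @return A list of class `blup_estimate`: `bhat`, `current` (both named by
#'   marker, `NA` for inestimable markers), `n_obs` per marker.
#' @export
blup <- function(fit, history, bp_med_at_s = 0, ages = NULL) {
  mks <- fit$markers
  K <- length(mks)
  h <- as.data.table(history)
  if (nrow(h)) {
    if (is.finite(fit$control$lookback)) h <- h[t_lm > -fit$control$lookback]
    h <- h[marker %in% mks]
  }
  bhat <- setNames(rep(0, K), mks)
  n_obs <- setNames(integer(K), mks)
  if (nrow(h)) {
    setkey(h, marker)
    X <- one_patient_design(fit, h, ages)
    mk <- match(h$marker, mks) - 1L
    n_obs[] <- tabulate(mk + 1L, nbins = K)
    V <- fit$G[mk + 1L, mk + 1L, drop = FALSE] +
      diag(fit$sigma2[mk + 1L], nrow(h))
    r <- h$value_std - as.numeric(X %*% fit$beta)
    w <- tryCatch(solve(V, r), error = function(e)
      stop("V is numerically singular (condition ~ ",
           format(kappa(V)), ")"))
    u <- as.numeric(rowsum(w, mks[mk + 1L])[, 1])
    names(u) <- rownames(rowsum(w, mks[mk + 1L]))
    uu <- setNames(rep(0, K), mks)
    uu[names(u)] <- u
    bhat[] <- as.numeric(fit$G %*% uu)
  }
  current <- current_from_bhat(fit, matrix(bhat, 1), bp_med_at_s,
                               rates = blup_rates(fit, h))
  out <- list(bhat = bhat, current = setNames(as.numeric(current), mks),
              n_obs = n_obs)
  full <- setNames(rep(NA_real_, length(MARKERS)), MARKERS)
  for (nm in c("bhat", "current")) {
    x <- full
    x[mks] <- out[[nm]]
    out[[nm]] <- x
  }
  structure(out, class = "blup_estimate")
}

blup_rates <- function(fit, h) {
  if (!fit$control$visit_rate_covariate) return(NULL)
  r <- setNames(rep(0, length(fit$markers)), fit$markers)
  if (nrow(h)) {
    for (k in fit$markers)
      r[k] <- annual_visit_rate(fit$s + h[marker == k, t_lm], fit$s)
  }
  matrix(r, 1, dimnames = list(NULL, fit$markers))
}

one_patient_design <- function(fit, h, ages = NULL) {
  mks <- fit$markers
  X <- matrix(0, nrow(h), length(fit$beta),
              dimnames = list(NULL, names(fit$beta)))
  for (k in mks) {
    ind <- as.numeric(h$marker == k)
    if (paste0("mu_", k) %in% colnames(X)) X[, paste0("mu_", k)] <- ind
    if (paste0("slope_", k) %in% colnames(X))
      X[, paste0("slope_", k)] <- ind * h$t_lm
    if (paste0("rate_", k) %in% colnames(X)) {
      a <- if (is.null(ages)) fit$s + h$t_lm else ages
      X[, paste0("rate_", k)] <- ind * annual_visit_rate(a[h$marker == k], fit$s)
    }
  }
  if ("bp_med_sbp" %in% colnames(X))
    X[, "bp_med_sbp"] <- as.numeric(h$marker == "sbp") * h$bp_med_at_meas
  X
}

current_from_bhat <- function(fit, bhat, bp_med_at_s, rates = NULL) {
  mks <- fit$markers
  n <- nrow(bhat)
  cur <- matrix(NA_real_, n, length(mks), dimnames = list(NULL, mks))
  for (j in seq_along(mks)) {
    k <- mks[j]
    mu <- paste0("mu_", k)
    if (!mu %in% names(fit$beta)) next
    val <- fit$beta[[mu]] + bhat[, j]
    if (k == "sbp" && "bp_med_sbp" %in% names(fit$beta))
      val <- val + fit$beta[["bp_med_sbp"]] * bp_med_at_s
    rk <- paste0("rate_", k)
    if (!is.null(rates) && rk %in% names(fit$beta))
      val <- val + fit$beta[[rk]] * rates[, k]
    cur[, j] <- val
  }
  cur
}

#' Estimated current risk-factor values for a whole landmark dataset
#'
#' Applies the empirical-Bayes BLUP to every eligible patient in `ld`
#' (both sexes use their own fit; this function handles one sex stratum,
#' matching `fit$sex`).  Patients with no in-window measurements receive the
#' fixed-effect prediction.
#'
#' @param fit An [fit_mlmm()] object.
#' @param ld A [build_landmark_dataset()] for the same landmark age (checked).
#' @return A `data.table` with `patient_id`, `cur_<marker>` columns and
#'   per-marker observation counts `nobs_<marker>`.
#' @export
estimate_current_values <- function(fit, ld) {
  if (!identical(fit$s, ld$s))
    stop("landmark age mismatch: fit at s = ", fit$s, ", data at s = ", ld$s)
  control <- fit$control
  d <- mlmm_design(ld, fit$sex, control, markers = fit$markers)
  # align the new design's columns with the fitted beta
  X <- d$X
  miss <- setdiff(names(fit$beta), colnames(X))
  if (length(miss)) {
    X <- cbind(X, matrix(0, nrow(X), length(miss),
                         dimnames = list(NULL, miss)))
  }
  X <- X[, names(fit$beta), drop = FALSE]
  bhat <- mlmm_blup_cpp(d$y, X, d$marker, d$pstart, fit$G, fit$sigma2,
                        fit$beta)
  rates <- NULL
  if (control$visit_rate_covariate) {
    rates <- matrix(0, length(d$patient_ids), length(fit$markers),
                    dimnames = list(NULL, fit$markers))
    if (!is.null(d$rates)) {
      ri <- match(d$patient_ids, d$rates$patient_id)
      for (k in fit$markers) {
        rv <- d$rates[[k]][ri]
        rv[is.na(rv)] <- 0
        rates[, k] <- rv
      }
    }
  }
  cur <- current_from_bhat(fit, bhat, d$info$bp_med, rates)
  out <- data.table(patient_id = d$patient_ids)
  for (j in seq_along(fit$markers)) {
    k <- fit$markers[j]
    out[, (paste0("cur_", k)) := cur[, j]]
  }
  cnt <- ld$history[patient_id %in% d$patient_ids,
                    .N, by = .(patient_id, marker)]
  for (k in MARKERS) {
    nk <- cnt[marker == k][match(out$patient_id, patient_id), N]
    nk[is.na(nk)] <- 0L
    out[, (paste0("nobs_", k)) := nk]
  }
  out[]
}

#' @export
print.mlmm_fit <- function(x, ...) {
  cat("Stage-1 multivariate LMM (s =", x$s, ",", x$sex, ")\n")
  cat("  patients:", x$n_patients, " observations:", x$n_obs,
      " logLik:", format(x$logLik), " converged:", x$converged, "\n")
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  cat("  G:\n")
  print(round(x$G, 4))
  cat("  sigma2:", paste(names(x$sigma2), round(x$sigma2, 4),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}
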
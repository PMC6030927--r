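# Stage 1: marginal ML fitting of the multivariate LMM and empirical-Bayes
# BLUP prediction of current risk-factor values.

test_that("with G fixed to zero and no slopes the fit degenerates to per-marker least squares", {
  set.seed(101)
  n <- 40
  hist <- rbindlist(lapply(seq_len(n), function(i) {
    data.table(patient_id = i, marker = rep(MK, each = 2),
               age = 55 + runif(8, -10, 0), value_std = rnorm(8),
               t_lm = runif(8, -10, 0) * 0, bp_med_at_meas = 0)
  }))
  hist[, t_lm := age - 60]
  info <- data.table(patient_id = seq_len(n), practice_id = 1L, sex = "male",
                     lm_age = 60, diabetes = 0, bp_med = 0,
                     follow_time = 10, event = 0)
  ld <- mk_landmark_dataset(info, hist, s = 60)
  ctl <- mlmm_control(fix_G = matrix(0, 4, 4, dimnames = list(MK, MK)),
                      slopes = FALSE, n_starts = 1)
  f <- fit_mlmm(ld, "male", ctl)
  for (k in MK) {
    y <- hist[marker == k, value_std]
    expect_equal(unname(f$beta[[paste0("mu_", k)]]), mean(y), tolerance = 1e-5)
    # ML variance uses divisor n
    expect_equal(unname(f$sigma2[[k]]), mean((y - mean(y))^2),
                 tolerance = 1e-4)
  }
})

test_that("single-marker balanced fit matches the closed-form one-way ML estimates", {
  set.seed(102)
  n <- 60; m <- 5
  sb2 <- 0.6; se2 <- 0.3
  b <- rnorm(n, sd = sqrt(sb2))
  hist <- rbindlist(lapply(seq_len(n), function(i) {
    data.table(patient_id = i, marker = "sbp", age = 60,
               value_std = 1.5 + b[i] + rnorm(m, sd = sqrt(se2)),
               t_lm = 0, bp_med_at_meas = 0)
  }))
  info <- data.table(patient_id = seq_len(n), practice_id = 1L, sex = "male",
                     lm_age = 60, diabetes = 0, bp_med = 0,
                     follow_time = 10, event = 0)
  ld <- mk_landmark_dataset(info, hist, s = 60)
  f <- fit_mlmm(ld, "male", mlmm_control(slopes = FALSE))
  # closed-form ML for the balanced one-way random-intercept model:
  # sigma_e^2 = SSW / (n (m - 1));  sigma_e^2 + m sigma_b^2 = m/n * sum (ybar_i - ybar)^2
  Y <- matrix(hist$value_std, nrow = m)
  ybar_i <- colMeans(Y)
  ssw <- sum((t(Y) - ybar_i)^2)
  se2_hat <- ssw / (n * (m - 1))
  tot <- m * sum((ybar_i - mean(Y))^2) / n
  sb2_hat <- (tot - se2_hat) / m
  expect_equal(unname(f$beta[["mu_sbp"]]), mean(Y), tolerance = 1e-5)
  expect_equal(unname(f$sigma2[["sbp"]]), se2_hat, tolerance = 1e-4)
  expect_equal(unname(f$G["sbp", "sbp"]), sb2_hat, tolerance = 1e-3)
  expect_equal(f$inestimable, setdiff(MK, "sbp"))
})

test_that("BLUP equals the direct conditional-MVN oracle over random configurations", {
  set.seed(103)
  for (rep in 1:25) {
    G <- random_psd(4, scale = runif(1, 0.3, 1.2))
    dimnames(G) <- list(MK, MK)
    sigma2 <- setNames(runif(4, 0.1, 0.8), MK)
    beta <- setNames(rnorm(9, sd = 0.5),
                     c(paste0("mu_", MK), paste0("slope_", MK), "bp_med_sbp"))
    fit <- manual_mlmm_fit(beta, G, sigma2)
    n_obs <- sample(1:6, 1)
    mki <- sample(1:4, n_obs, replace = TRUE)
    tt <- runif(n_obs, -15, 0)
    bp <- rbinom(n_obs, 1, 0.3)
    y <- rnorm(n_obs)
    hist <- data.table(marker = MK[mki], t_lm = tt, value_std = y,
                       bp_med_at_meas = bp)
    est <- blup(fit, hist, bp_med_at_s = 1)
    # oracle: joint covariance of (b, y), conditioned directly
    X <- matrix(0, n_obs, 9, dimnames = list(NULL, names(beta)))
    for (r in seq_len(n_obs)) {
      X[r, paste0("mu_", MK[mki[r]])] <- 1
      X[r, paste0("slope_", MK[mki[r]])] <- tt[r]
      if (MK[mki[r]] == "sbp") X[r, "bp_med_sbp"] <- bp[r]
    }
    b_or <- oracle_blup(G, sigma2, beta, X, mki, y)
    expect_equal(unname(est$bhat[MK]), b_or, tolerance = 1e-8)
  }
})

test_that("BLUP with empty history is the prior mean and cross-marker borrowing matches conditioning", {
  G <- default_G()
  sigma2 <- setNames(rep(0.3, 4), MK)
  beta <- setNames(c(0.2, -0.1, 0.4, 0.1, 0, 0, 0, 0, -0.4),
                   c(paste0("mu_", MK), paste0("slope_", MK), "bp_med_sbp"))
  fit <- manual_mlmm_fit(beta, G, sigma2)
  empty <- data.table(marker = character(), t_lm = numeric(),
                      value_std = numeric(), bp_med_at_meas = numeric())
  est <- blup(fit, empty, bp_med_at_s = 1)
  expect_equal(unname(est$bhat), rep(0, 4))
  expect_equal(unname(est$current[["sbp"]]),
               beta[["mu_sbp"]] + beta[["bp_med_sbp"]])
  expect_equal(unname(est$current[["tchol"]]), beta[["mu_tchol"]])

  # classic shrinkage with diagonal G and m repeats of one marker at t = 0
  Gd <- diag(c(0.5, 0.6, 0.7, 0.4)); dimnames(Gd) <- list(MK, MK)
  fit2 <- manual_mlmm_fit(beta, Gd, sigma2)
  m <- 4
  yv <- c(1.3, 0.9, 1.1, 1.5)
  h <- data.table(marker = "tchol", t_lm = 0, value_std = yv,
                  bp_med_at_meas = 0)
  est2 <- blup(fit2, h)
  shrink <- Gd["tchol", "tchol"] /
    (Gd["tchol", "tchol"] + sigma2[["tchol"]] / m)
  expect_equal(unname(est2$bhat[["tchol"]]),
               shrink * (mean(yv) - beta[["mu_tchol"]]), tolerance = 1e-10)
  # unobserved markers stay at 0 under diagonal G
  expect_equal(unname(est2$bhat[c("smoking", "sbp", "hdlc")]), rep(0, 3))

  # nonzero sbp-tchol covariance shifts the unobserved marker
  est3 <- blup(fit, data.table(marker = "sbp", t_lm = 0, value_std = 2,
                               bp_med_at_meas = 0))
  expect_gt(unname(est3$bhat[["tchol"]]), 0)
})

test_that("shrinkage grows with data and a residual of zero leaves the BLUP at zero", {
  G <- diag(0.5, 4); dimnames(G) <- list(MK, MK)
  sigma2 <- setNames(rep(0.4, 4), MK)
  beta <- setNames(c(0.3, 0.1, 0.2, 0, rep(0, 4), 0),
                   c(paste0("mu_", MK), paste0("slope_", MK), "bp_med_sbp"))
  fit <- manual_mlmm_fit(beta, G, sigma2)
  # an observation exactly at the fixed-effect prediction: zero residual
  h0 <- data.table(marker = "sbp", t_lm = 0, value_std = beta[["mu_sbp"]],
                   bp_med_at_meas = 0)
  expect_equal(unname(blup(fit, h0)$bhat[["sbp"]]), 0)
  # |bhat| increases toward the raw residual mean as m grows
  devs <- vapply(c(1, 3, 10, 50), function(m) {
    h <- data.table(marker = "sbp", t_lm = 0, value_std = rep(1.3, m),
                    bp_med_at_meas = 0)
    unname(blup(fit, h)$bhat[["sbp"]])
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
  expect_lt(max(devs), 1.3 - beta[["mu_sbp"]] + 1e-9)
  # as the residual variance vanishes, the current value approaches the observation
  fit_small <- manual_mlmm_fit(beta, G, setNames(rep(1e-10, 4), MK))
  h1 <- data.table(marker = "sbp", t_lm = 0, value_std = 1.11,
                   bp_med_at_meas = 0)
  expect_equal(unname(blup(fit_small, h1)$current[["sbp"]]), 1.11,
               tolerance = 1e-6)
})

test_that("batch current values equal row-by-row BLUPs", {
  set.seed(104)
  sim <- simulate_mlmm_data(
    40, beta0 = c(0.2, 0.3, -0.1, 0), beta1 = c(0, 0.02, 0.01, -0.01),
    gamma = -0.4, G = default_G(), sigma2 = c(0.2, 0.4, 0.3, 0.25),
    m_per_marker = c(1, 4))
  f <- fit_mlmm(sim$ld, "male", mlmm_control(n_starts = 1))
  batch <- estimate_current_values(f, sim$ld)
  for (i in c(1, 7, 23)) {
    h <- sim$ld$history[patient_id == i]
    single <- blup(f, h, bp_med_at_s = sim$ld$info$bp_med[i])
    for (k in MK)
      expect_equal(batch[patient_id == i][[paste0("cur_", k)]],
                   unname(single$current[[k]]), tolerance = 1e-10)
  }
  expect_error(estimate_current_values(f, mk_landmark_dataset(
    sim$ld$info, sim$ld$history, s = 65)), "landmark age mismatch")
})

test_that("joint fit with near-diagonal G agrees with separate univariate fits", {
  set.seed(105)
  Gd <- diag(c(0.5, 0.6, 0.4, 0.45)); dimnames(Gd) <- list(MK, MK)
  sim <- simulate_mlmm_data(
    150, beta0 = c(0.2, 0.3, -0.1, 0), beta1 = c(-0.01, 0.02, 0.01, 0),
    gamma = -0.4, G = Gd, sigma2 = c(0.3, 0.4, 0.3, 0.25),
    m_per_marker = c(2, 5))
  joint <- fit_mlmm(sim$ld, "male", mlmm_control(n_starts = 1))
  cur_joint <- estimate_current_values(joint, sim$ld)
  for (k in c("sbp", "hdlc")) {
    hist_k <- sim$ld$history[marker == k]
    ld_k <- mk_landmark_dataset(sim$ld$info, hist_k, s = 60)
    f_k <- fit_mlmm(ld_k, "male", mlmm_control(n_starts = 1))
    cur_k <- estimate_current_values(f_k, ld_k)
    d <- cur_joint[[paste0("cur_", k)]] - cur_k[[paste0("cur_", k)]]
    expect_lt(max(abs(d)), 0.12)
  }
})

test_that("the lookback option truncates history and is inert when all data are recent", {
  set.seed(106)
  sim <- simulate_mlmm_data(
    30, beta0 = c(0.2, 0.3, -0.1, 0), beta1 = rep(0, 4), gamma = 0,
    G = default_G(), sigma2 = rep(0.3, 4), m_per_marker = c(2, 3))
  recent <- sim$ld$history[t_lm > -10]
  ld_recent <- mk_landmark_dataset(sim$ld$info, recent, s = 60)
  f_inf <- fit_mlmm(ld_recent, "male", mlmm_control(n_starts = 1))
  f_10 <- fit_mlmm(ld_recent, "male",
                   mlmm_control(lookback = 10, n_starts = 1))
  expect_equal(f_inf$beta, f_10$beta, tolerance = 1e-10)
  expect_equal(f_inf$logLik, f_10$logLik, tolerance = 1e-10)
  # with older data present the two differ in the rows used
  f_all <- fit_mlmm(sim$ld, "male", mlmm_control(n_starts = 1))
  f_win <- fit_mlmm(sim$ld, "male", mlmm_control(lookback = 10, n_starts = 1))
  expect_lt(f_win$n_obs, f_all$n_obs)
})

test_that("annual visit rate counts the 5-year window and truncates at age 30", {
  expect_equal(annual_visit_rate(seq(55.5, 60, by = 0.5), 60), 10 / 5)
  expect_equal(annual_visit_rate(numeric(0), 60), 0)
  # s = 32: window truncated at 30, length 2
  expect_equal(annual_visit_rate(c(30.5, 31, 31.5, 32), 32), 2)
  # the window is the half-open interval (s-5, s]: 54.9 and 50 fall outside
  expect_equal(annual_visit_rate(c(50, 54.9, 55 + 1e-9, 60), 60), 2 / 5)
})

test_that("per-observation log-likelihood at the truth does not degrade with more data", {
  set.seed(107)
  gen <- function(n) simulate_mlmm_data(
    n, beta0 = c(0.2, 0.3, -0.1, 0), beta1 = c(0, 0.02, 0, 0), gamma = -0.4,
    G = default_G(), sigma2 = c(0.2, 0.4, 0.3, 0.25), m_per_marker = c(2, 4))
  ll_per_obs <- vapply(c(100, 400), function(n) {
    sim <- gen(n)
    f <- fit_mlmm(sim$ld, "male", mlmm_control(n_starts = 1))
    f$logLik / f$n_obs
  }, numeric(1))
  expect_lt(abs(ll_per_obs[1] - ll_per_obs[2]), 0.15)
})

test_that("the REML switch fits and shrinks variances less than ML", {
  set.seed(110)
  n <- 50; m <- 3
  b <- rnorm(n, sd = sqrt(0.5))
  hist <- rbindlist(lapply(seq_len(n), function(i) {
    data.table(patient_id = i, marker = "sbp", age = 60,
               value_std = 0.4 + b[i] + rnorm(m, sd = sqrt(0.3)),
               t_lm = 0, bp_med_at_meas = 0)
  }))
  info <- data.table(patient_id = seq_len(n), practice_id = 1L, sex = "male",
                     lm_age = 60, diabetes = 0, bp_med = 0,
                     follow_time = 10, event = 0)
  ld <- mk_landmark_dataset(info, hist, s = 60)
  f_ml <- fit_mlmm(ld, "male", mlmm_control(slopes = FALSE, n_starts = 1))
  f_reml <- fit_mlmm(ld, "male",
                     mlmm_control(slopes = FALSE, n_starts = 1, reml = TRUE))
  # the REML criterion corrects the downward ML bias of the between-patient
  # variance from estimating the mean
  expect_gt(f_reml$G["sbp", "sbp"], f_ml$G["sbp", "sbp"])
  expect_equal(f_reml$beta[["mu_sbp"]], f_ml$beta[["mu_sbp"]],
               tolerance = 1e-3)
})

test_that("the joint fit agrees with an established mixed-model implementation", {
  # cross-check against nlme: same model expressed as a heteroscedastic LMM
  # with a general random-intercept covariance across markers
  set.seed(109)
  sim <- simulate_mlmm_data(
    80, beta0 = c(0.2, 0.5, -0.3, 0.1), beta1 = c(-0.01, 0.02, 0.015, -0.005),
    gamma = -0.4, G = default_G(), sigma2 = c(0.15, 0.45, 0.3, 0.25),
    m_per_marker = c(2, 4))
  f <- fit_mlmm(sim$ld, "male", mlmm_control(n_starts = 1))
  h <- data.table::copy(sim$ld$history)
  h[, marker := factor(marker, levels = MK)]
  h[, bp_sbp := as.numeric(marker == "sbp") * bp_med_at_meas]
  lf <- nlme::lme(value_std ~ 0 + marker + marker:t_lm + bp_sbp,
                  random = ~ 0 + marker | patient_id,
                  weights = nlme::varIdent(form = ~ 1 | marker),
                  data = h, method = "ML",
                  control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                             msMaxIter = 200))
  expect_equal(f$logLik, as.numeric(logLik(lf)), tolerance = 1e-5)
  fe <- nlme::fixef(lf)
  expect_equal(unname(f$beta[paste0("mu_", MK)]),
               unname(fe[paste0("marker", MK)]), tolerance = 2e-3)
  expect_equal(unname(f$beta[["bp_med_sbp"]]), unname(fe[["bp_sbp"]]),
               tolerance = 5e-3)
})

test_that("visit-rate adjustment adds per-marker rate covariates", {
  set.seed(108)
  sim <- simulate_mlmm_data(
    60, beta0 = c(0.2, 0.3, -0.1, 0), beta1 = rep(0, 4), gamma = -0.3,
    G = default_G(), sigma2 = rep(0.3, 4), m_per_marker = c(2, 4))
  f <- fit_mlmm(sim$ld, "male",
                mlmm_control(visit_rate_covariate = TRUE, n_starts = 1))
  expect_true(any(grepl("^rate_", names(f$beta))))
  cur <- estimate_current_values(f, sim$ld)
  expect_true(all(is.finite(cur$cur_sbp)))
})
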
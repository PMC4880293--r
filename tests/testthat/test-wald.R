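# The Wald machinery is exercised on constructed fit objects so the
# arithmetic can be checked against hand-computed values; end-to-end
# calibration is covered by the acceptance suite.

fake_fit <- function(est, sd, cov4 = NULL) {
  free <- names(est)
  sd_full <- setNames(rep(NA_real_, 7), c(
    "mu_m_intercept", "mu_m_slope", "mu_d_intercept", "mu_d_slope",
    "eta_intercept", "eta_slope", "p"
  ))
  sd_full[names(sd)] <- sd
  cov <- diag(sd[free]^2, nrow = length(free))
  dimnames(cov) <- list(free, free)
  if (!is.null(cov4)) cov[rownames(cov4), colnames(cov4)] <- cov4
  model <- efficiency_model(
    mu_m = unname(est[c("mu_m_intercept", "mu_m_slope")]),
    mu_d = unname(est[c("mu_d_intercept", "mu_d_slope")]),
    eta = unname(est[c("eta_intercept", "eta_slope")]),
    p = unname(est["p"])
  )
  structure(
    list(
      model = model,
      fim = list(
        free = free, sd = sd_full, cov = cov,
        unreliable = setNames(rep(FALSE, 7), names(sd_full)),
        boundary = setNames(rep(FALSE, 7), names(sd_full)),
        singular = FALSE
      )
    ),
    class = "dyad_fit"
  )
}

full_est <- function(mu_m = c(0.8, 0), mu_d = c(0.3, 0), eta = c(0.05, 0), p = 0.5) {
  setNames(
    c(mu_m, mu_d, eta, p),
    c(
      "mu_m_intercept", "mu_m_slope", "mu_d_intercept", "mu_d_slope",
      "eta_intercept", "eta_slope", "p"
    )
  )
}

full_sd <- function(x = 0.01) {
  setNames(rep(x, 7), names(full_est()))
}

test_that("slope Wald test computes z = slope / sd with a normal tail", {
  fit <- fake_fit(full_est(eta = c(0.05, 0.05)), full_sd(0.01))
  res <- wald_slope_test(fit, "eta")
  expect_equal(res$statistic, 5)
  expect_equal(res$p.value, 2 * pnorm(-5))
  expect_true(res$reject)
  res0 <- wald_slope_test(fake_fit(full_est(), full_sd(0.01)), "mu_m")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_false(res0$reject)
})

test_that("slope test is refused when the slope is fixed or its sd unusable", {
  est <- full_est()
  sd <- full_sd()
  fit <- fake_fit(est, sd)
  fit$fim$free <- setdiff(fit$fim$free, "mu_d_slope")
  expect_true(wald_slope_test(fit, "mu_d")$refused)
  sd2 <- sd
  sd2["eta_slope"] <- 0
  expect_true(wald_slope_test(fake_fit(est, sd2), "eta")$refused)
  fit3 <- fake_fit(est, sd)
  fit3$fim$unreliable["mu_m_slope"] <- TRUE
  expect_true(wald_slope_test(fit3, "mu_m")$refused)
})

test_that("joint lambda test matches the delta-method chi-square", {
  # both lambda time-coefficients zero: statistic 0, p = 1
  fit0 <- fake_fit(full_est(mu_m = c(0.8, 0), mu_d = c(0.3, 0)), full_sd(0.01))
  res0 <- wald_lambda_joint_test(fit0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_false(res0$reject)

  # hand-computed case: diagonal covariance of the four mu parameters
  est <- full_est(mu_m = c(0.8, 0.01), mu_d = c(0.3, -0.02))
  sds <- full_sd(0.005)
  fit <- fake_fit(est, sds)
  res <- wald_lambda_joint_test(fit)
  a0 <- 0.8; a1 <- 0.01; b0 <- 0.3; b1 <- -0.02
  beta <- c(a1 + b1 - a0 * b1 - a1 * b0, -a1 * b1)
  G <- rbind(c(-b1, 1 - b0, -a1, 1 - a0), c(0, -b1, 0, -a1))
  V <- G %*% diag(rep(0.005^2, 4)) %*% t(G)
  W <- drop(t(beta) %*% solve(V) %*% beta)
  expect_equal(res$statistic, W, tolerance = 1e-10)
  expect_equal(res$p.value, pchisq(W, 2, lower.tail = FALSE))
  expect_equal(unname(res$estimate), beta)
  expect_equal(res$reject, W > qchisq(0.99, 2))
  # a slope that is large relative to its sd rejects
  sharp <- wald_lambda_joint_test(fake_fit(est, full_sd(0.001)))
  expect_gt(sharp$statistic, qchisq(0.99, 2))
  expect_true(sharp$reject)
})

test_that("joint lambda test is refused without free methylation slopes", {
  fit <- fake_fit(full_est(), full_sd())
  fit$fim$free <- setdiff(fit$fim$free, c("mu_m_slope", "mu_d_slope"))
  expect_true(wald_lambda_joint_test(fit)$refused)
})

test_that("lambda coefficients expand the quadratic identity", {
  model <- efficiency_model(mu_m = c(0.7, 0.02), mu_d = c(0.2, -0.01), eta = c(0, 0), p = 0)
  lam <- lambda_coefficients(model)
  for (t in 1:6) {
    e <- evaluate_efficiencies(model, t)
    expect_equal(
      unname(lam["lambda_0"] + lam["lambda_1"] * t + lam["lambda_2"] * t^2),
      e$lambda
    )
  }
})
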
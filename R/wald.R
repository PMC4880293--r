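# Wald tests on the fitted efficiency functions.
#
# With deep sequencing the MLEs are approximately unbiased and normal,
# so slope hypotheses are tested with normal Wald statistics and the
# joint hypothesis on the time coefficients of the total efficiency
# lambda(t) with a chi-square Wald statistic.

#' Wald test for a zero efficiency slope
#'
#' Tests `H0: slope = 0` for one of the three efficiency functions using
#' `z = slope / sd(slope)` with a two-sided normal p-value, by default at
#' the 1% level.
#'
#' @param fit A `"dyad_fit"` from [fit_efficiencies()] with an attached
#'   Fisher-information summary.
#' @param which One of `"mu_m"`, `"mu_d"`, `"eta"`.
#' @param alpha Test level (default 0.01).
#' @return An object of class `"dyad_wald"` with elements `statistic`,
#'   `p.value`, `reject`, `alpha`, or a refusal (`refused = TRUE` with a
#'   `reason`) when the slope is not estimated or its standard deviation
#'   is zero or unreliable.
#' @export
wald_slope_test <- function(fit, which = c("mu_m", "mu_d", "eta"), alpha = 0.01) {
  stopifnot(inherits(fit, "dyad_fit"))
  which <- match.arg(which)
  nm <- paste0(which, "_slope")
  refuse <- function(reason) {
    structure(
      list(
        parameter = nm, refused = TRUE, reason = reason,
        statistic = NA_real_, p.value = NA_real_, reject = NA, alpha = alpha
      ),
      class = "dyad_wald"
    )
  }
  if (is.null(fit$fim)) {
    return(refuse("fit carries no Fisher-information summary"))
  }
  if (!nm %in% fit$fim$free) {
    return(refuse("slope was not a free parameter in this fit"))
  }
  sd <- fit$fim$sd[nm]
  if (!is.finite(sd) || sd <= 0) {
    return(refuse("slope standard deviation is zero or undefined"))
  }
  if (fit$fim$unreliable[nm]) {
    return(refuse("information matrix unreliable for this parameter"))
  }
  slope <- coef(fit$model)[nm]
  z <- unname(slope / sd)
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(
      parameter = nm, refused = FALSE, estimate = unname(slope), sd = unname(sd),
      statistic = z, p.value = p, reject = p < alpha, alpha = alpha
    ),
    class = "dyad_wald"
  )
}

#' Joint Wald test for a time-constant total methylation efficiency
#'
#' The total efficiency on hemimethylated dyads,
#' `lambda(t) = mu_m(t) + mu_d(t) - mu_m(t) * mu_d(t)`, is quadratic in
#' `t` when the two methylation efficiencies are linear:
#' `lambda(t) = lambda_0 + lambda_1 t + lambda_2 t^2` (see
#' [lambda_coefficients()]).  This tests
#' `H0: lambda_1 = 0 and lambda_2 = 0` with a chi-square Wald statistic
#' on 2 degrees of freedom, using the delta-method covariance of
#' `(lambda_1, lambda_2)` derived from the observed Fisher information.
#'
#' @inheritParams wald_slope_test
#' @return A `"dyad_wald"` object (`statistic`, `p.value`, `reject`,
#'   `df = 2`) or a refusal.
#' @export
wald_lambda_joint_test <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "dyad_fit"))
  refuse <- function(reason) {
    structure(
      list(
        parameter = "lambda_1, lambda_2", refused = TRUE, reason = reason,
        statistic = NA_real_, p.value = NA_real_, reject = NA, alpha = alpha
      ),
      class = "dyad_wald"
    )
  }
  if (is.null(fit$fim)) {
    return(refuse("fit carries no Fisher-information summary"))
  }
  need <- c("mu_m_intercept", "mu_m_slope", "mu_d_intercept", "mu_d_slope")
  if (!all(need %in% fit$fim$free)) {
    return(refuse("both methylation efficiencies must be fitted with free slopes"))
  }
  a0 <- fit$model$mu_m[1]
  a1 <- fit$model$mu_m[2]
  b0 <- fit$model$mu_d[1]
  b1 <- fit$model$mu_d[2]
  lam <- lambda_coefficients(fit$model)
  beta <- lam[c("lambda_1", "lambda_2")]
  # gradient of (lambda_1, lambda_2) wrt (a0, a1, b0, b1)
  G <- rbind(
    lambda_1 = c(-b1, 1 - b0, -a1, 1 - a0),
    lambda_2 = c(0, -b1, 0, -a1)
  )
  S <- fit$fim$cov[need, need]
  V <- G %*% S %*% t(G)
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) {
    if (all(abs(beta) < 1e-12)) {
      # degenerate covariance but the null value itself: statistic 0
      Vinv <- matrix(0, 2, 2)
    } else {
      Vinv <- pracma::pinv(V)
    }
  }
  W <- drop(t(beta) %*% Vinv %*% beta)
  p <- stats::pchisq(W, df = 2, lower.tail = FALSE)
  structure(
    list(
      parameter = "lambda_1, lambda_2", refused = FALSE,
      estimate = beta, covariance = V,
      statistic = W, df = 2, p.value = p, reject = p < alpha, alpha = alpha
    ),
    class = "dyad_wald"
  )
}

#' @export
print.dyad_wald <- function(x, ...) {
  if (isTRUE(x$refused)) {
    cat("Wald test on", x$parameter, "refused:", x$reason, "\n")
    return(invisible(x))
  }
  cat("Wald test, H0:", x$parameter, "= 0\n")
  if (!is.null(x$df)) {
    cat("chi-square statistic:", format(x$statistic), "on", x$df, "df\n")
  } else {
    cat("z statistic:", format(x$statistic), "\n")
  }
  cat(
    "p-value:", format.pval(x$p.value), "->",
    if (isTRUE(x$reject)) "reject" else "fail to reject",
    "at alpha =", x$alpha, "\n"
  )
  invisible(x)
}
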
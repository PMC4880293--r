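# Time-linear enzymatic efficiency functions.

#' Enzymatic efficiency model
#'
#' Bundles the seven unknown parameters of the dyad chain: intercept/slope
#' pairs for the maintenance methylation efficiency `mu_m(t)`, the de novo
#' efficiency `mu_d(t)` and the hydroxylation efficiency `eta(t)`, each of
#' the form `intercept + slope * t` in the division index `t`, plus the
#' probability `p` that a hemi-hydroxylated dyad escapes the maintenance
#' machinery.
#'
#' @param mu_m,mu_d,eta Numeric of length 1 (constant efficiency) or 2
#'   (`c(intercept, slope)`).
#' @param p Non-recognition probability in \[0, 1\].
#' @return An object of class `"efficiency_model"`.
#' @examples
#' m <- efficiency_model(mu_m = 0.8, mu_d = c(0.3, -0.02), eta = c(0.05, 0.03), p = 1)
#' evaluate_efficiencies(m, t = 3)
#' @export
efficiency_model <- function(mu_m = c(0, 0), mu_d = c(0, 0), eta = c(0, 0), p = 0) {
  as_pair <- function(x, name) {
    if (!is.numeric(x) || !length(x) %in% 1:2 || anyNA(x)) {
      stop("`", name, "` must be numeric of length 1 or 2", call. = FALSE)
    }
    if (length(x) == 1L) x <- c(x, 0)
    unname(x)
  }
  .check_prob(p, "p")
  structure(
    list(
      mu_m = as_pair(mu_m, "mu_m"),
      mu_d = as_pair(mu_d, "mu_d"),
      eta = as_pair(eta, "eta"),
      p = unname(p)
    ),
    class = "efficiency_model"
  )
}

#' Evaluate the efficiency functions at a division index
#'
#' @param model An [efficiency_model()].
#' @param t Division index (>= 1 for use in a transition matrix).
#' @param clamp If `TRUE`, values outside \[0, 1\] are clamped; otherwise
#'   values more than 1e-9 outside raise an error (values within numerical
#'   tolerance are always clamped).
#' @return List with elements `mu_m`, `mu_d`, `eta`, `lambda`
#'   (`mu_m + mu_d - mu_m * mu_d`, the total methylation efficiency on a
#'   hemimethylated dyad) and `p`.
#' @export
evaluate_efficiencies <- function(model, t, clamp = FALSE) {
  stopifnot(inherits(model, "efficiency_model"))
  val <- function(pair, name) {
    x <- pair[1] + pair[2] * t
    if (x < 0 || x > 1) {
      if (!clamp && (x < -1e-9 || x > 1 + 1e-9)) {
        stop(name, "(t) = ", format(x), " outside [0, 1] at t = ", t, call. = FALSE)
      }
      x <- min(max(x, 0), 1)
    }
    x
  }
  mu_m <- val(model$mu_m, "mu_m")
  mu_d <- val(model$mu_d, "mu_d")
  eta <- val(model$eta, "eta")
  list(
    mu_m = mu_m, mu_d = mu_d, eta = eta,
    lambda = mu_m + mu_d - mu_m * mu_d,
    p = min(max(model$p, 0), 1)
  )
}

#' @export
coef.efficiency_model <- function(object, ...) {
  c(
    mu_m_intercept = object$mu_m[1], mu_m_slope = object$mu_m[2],
    mu_d_intercept = object$mu_d[1], mu_d_slope = object$mu_d[2],
    eta_intercept = object$eta[1], eta_slope = object$eta[2],
    p = object$p
  )
}

#' @export
print.efficiency_model <- function(x, digits = 4, ...) {
  cat("Efficiency model (f(t) = intercept + slope * t):\n")
  tab <- rbind(
    mu_m = x$mu_m, mu_d = x$mu_d, eta = x$eta
  )
  colnames(tab) <- c("intercept", "slope")
  print(round(tab, digits))
  cat("p (maintenance non-recognition at hemi-5hmC):", round(x$p, digits), "\n")
  invisible(x)
}

#' Coefficients of the total methylation efficiency lambda(t)
#'
#' With `mu_m(t)` and `mu_d(t)` linear in `t`, the total efficiency
#' `lambda(t) = mu_m(t) + mu_d(t) - mu_m(t) * mu_d(t)` is quadratic in
#' `t`; this returns its coefficients `c(beta0, beta1, beta2)` such that
#' `lambda(t) = beta0 + beta1 * t + beta2 * t^2`.
#'
#' @param model An [efficiency_model()].
#' @return Named numeric vector `c(lambda_0, lambda_1, lambda_2)`.
#' @export
lambda_coefficients <- function(model) {
  stopifnot(inherits(model, "efficiency_model"))
  a0 <- model$mu_m[1]
  a1 <- model$mu_m[2]
  b0 <- model$mu_d[1]
  b1 <- model$mu_d[2]
  c(
    lambda_0 = a0 + b0 - a0 * b0,
    lambda_1 = a1 + b1 - a0 * b1 - a1 * b0,
    lambda_2 = -a1 * b1
  )
}
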
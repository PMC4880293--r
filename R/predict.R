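# Fitted time courses: hidden-state distributions, observable
# distributions and the summary levels usually plotted for hairpin data.

#' Predicted hidden and observable time course of a fit
#'
#' Propagates the fitted (or supplied) initial distribution through the
#' fitted transition matrices and returns, per requested day, the
#' hidden-state probabilities, the predicted BS and oxBS read-pair
#' distributions, the summary levels (fully methylated `mm`,
#' hemimethylated `um + mu`, unmethylated `uu`, total hydroxylated, and
#' per-strand 5hmC/5mC levels) and the total methylation efficiency
#' `lambda(t) = mu_m(t) + mu_d(t) - mu_m(t) * mu_d(t)` in force during
#' the day's division cycle.
#'
#' @param fit A `"dyad_fit"` from [fit_efficiencies()].
#' @param days Days to predict; defaults to the observation days of the
#'   fitted dataset.  Days beyond the fitted range are allowed; the
#'   efficiency functions are then clamped into \[0, 1\].
#' @return Data frame with one row per day.
#' @export
predict_timecourse <- function(fit, days = NULL) {
  stopifnot(inherits(fit, "dyad_fit"))
  if (is.null(days)) days <- fit$data$days
  days <- sort(unique(days))
  if (any(days < 0 | days != round(days))) stop("days must be nonnegative integers")
  dpd <- fit$data$divisions_per_day
  t_need <- max(days) * dpd
  pis <- .propagate_table(fit$pi0, fit$model, max(t_need, 1L), clamp = TRUE)

  rows <- lapply(days, function(d) {
    t <- d * dpd
    pi_t <- pis[t + 1L, ]
    hidden <- as.data.frame(t(pi_t))
    obs_bs <- observable_distribution(pi_t, get_profile(fit$data, d, "bs"))
    obs_ox <- observable_distribution(pi_t, get_profile(fit$data, d, "ox"))
    names(obs_bs) <- paste0("bs_", OBS_STATES)
    names(obs_ox) <- paste0("ox_", OBS_STATES)
    summ <- summarize_hidden(pi_t)
    lambda_t <- if (t >= 1) {
      evaluate_efficiencies(fit$model, t, clamp = TRUE)$lambda
    } else {
      NA_real_
    }
    cbind(
      data.frame(day = d, t = t), hidden,
      as.data.frame(t(obs_bs)), as.data.frame(t(obs_ox)),
      as.data.frame(t(summ)), data.frame(lambda = lambda_t)
    )
  })
  do.call(rbind, rows)
}

#' Fitted efficiency functions over time
#'
#' Evaluates the fitted `mu_m(t)`, `mu_d(t)`, `eta(t)` and `lambda(t)` at
#' the requested division indices, for tables in the style of the usual
#' efficiency-over-time plots.
#'
#' @param model An [efficiency_model()] (or a `"dyad_fit"`).
#' @param t Division indices (default `1:6`).
#' @return Data frame with columns `t`, `mu_m`, `mu_d`, `eta`, `lambda`,
#'   `p`.
#' @export
efficiency_timecourse <- function(model, t = 1:6) {
  if (inherits(model, "dyad_fit")) model <- model$model
  stopifnot(inherits(model, "efficiency_model"))
  rows <- lapply(t, function(tt) {
    e <- evaluate_efficiencies(model, tt, clamp = TRUE)
    data.frame(
      t = tt, mu_m = e$mu_m, mu_d = e$mu_d, eta = e$eta,
      lambda = e$lambda, p = e$p
    )
  })
  do.call(rbind, rows)
}
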
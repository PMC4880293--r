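# Negative log-likelihoods of the two-experiment hidden Markov model.
#
# Both treatments observe the same hidden chain (the BS and oxBS pools
# are split from one cell population) through different emission
# matrices, and observations at distinct timepoints are independent
# because each measurement samples a vanishing fraction of a large pool.

#' Negative log-likelihood of the initial distribution (day 0)
#'
#' `-log L1(pi0)` where
#' `L1 = prod_j pi_bs(j, 0)^n_bs(j, 0) * pi_ox(j, 0)^n_ox(j, 0)`,
#' with `pi_bs(0) = pi0 %*% E_bs(0)` and `pi_ox(0) = pi0 %*% E_ox(0)`.
#' An observable state with positive count but zero predicted probability
#' yields `+Inf` (returned, not raised).
#'
#' @param pi0 Hidden-state distribution (see [as_hidden_distribution()]).
#' @param data An [observation_dataset()] containing day-0 counts for
#'   both treatments.
#' @return Scalar negative log-likelihood.
#' @export
neg_log_likelihood_initial <- function(pi0, data) {
  stopifnot(inherits(data, "observation_dataset"))
  pi0 <- as_hidden_distribution(pi0)
  nll <- 0
  seen <- FALSE
  for (tr in c("bs", "ox")) {
    n <- counts_for(data, 0, tr)
    if (is.null(n)) next
    seen <- TRUE
    pred <- as.vector(pi0 %*% emission_matrix(get_profile(data, 0, tr)))
    pos <- n > 0
    if (any(pos & pred <= 0)) {
      return(Inf)
    }
    nll <- nll - sum(n[pos] * log(pred[pos]))
  }
  if (!seen) {
    stop("dataset has no day-0 counts; cannot evaluate the initial likelihood")
  }
  nll
}

# Hidden-state distributions at every division index up to the last
# observation; row t + 1 holds pi(t).  Uses the fast unchecked kernels;
# an efficiency outside [0, 1] (beyond numerical tolerance, with
# clamp = FALSE) raises the same error as transition_matrix().
.propagate_table <- function(pi0, model, t_max, clamp = FALSE) {
  pis <- matrix(NA_real_, t_max + 1L, 9L, dimnames = list(NULL, DYAD_STATES))
  pis[1L, ] <- pi0
  pi_t <- matrix(pi0, 1L, 9L)
  D <- .D_fast()
  p <- min(max(model$p, 0), 1)
  for (k in seq_len(t_max)) {
    mu_m <- .eff_at(model$mu_m, k, clamp)
    mu_d <- .eff_at(model$mu_d, k, clamp)
    eta <- .eff_at(model$eta, k, clamp)
    if (is.na(mu_m) || is.na(mu_d) || is.na(eta)) {
      stop("efficiency outside [0, 1] at division t = ", k, call. = FALSE)
    }
    pi_t <- ((pi_t %*% D) %*% .M_fast(mu_m, mu_d, p)) %*% .H_fast(eta)
    pis[k + 1L, ] <- pi_t
  }
  pis
}

#' Negative log-likelihood of the dynamics (days > 0)
#'
#' `-log L2(v)` where
#' `L2 = prod_{t in T_obs \ {0}} prod_j pi_bs(j, t)^n_bs(j, t) *
#' pi_ox(j, t)^n_ox(j, t)` and
#' `pi(t) = pi0 %*% P(1) %*% ... %*% P(t)`.  Division indices are
#' `day * divisions_per_day`.
#'
#' @param model An [efficiency_model()] (the parameter vector `v`).
#' @param pi0 Hidden-state distribution at day 0.
#' @param data An [observation_dataset()] with at least one day > 0.
#' @return Scalar negative log-likelihood (`+Inf` for a zero-probability
#'   observation).
#' @export
neg_log_likelihood_dynamics <- function(model, pi0, data) {
  stopifnot(inherits(data, "observation_dataset"))
  pi0 <- as_hidden_distribution(pi0)
  days <- setdiff(data$days, 0)
  if (!length(days)) stop("dataset has no post-day-0 counts")
  dpd <- data$divisions_per_day
  pis <- .propagate_table(pi0, model, max(days) * dpd)
  nll <- 0
  for (d in days) {
    for (tr in c("bs", "ox")) {
      n <- counts_for(data, d, tr)
      if (is.null(n)) next
      pred <- as.vector(pis[d * dpd + 1L, ] %*% emission_matrix(get_profile(data, d, tr)))
      pos <- n > 0
      if (any(pos & pred <= 0)) {
        return(Inf)
      }
      nll <- nll - sum(n[pos] * log(pred[pos]))
    }
  }
  nll
}
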
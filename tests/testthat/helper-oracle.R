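# Independent oracles used by the tests.  These deliberately avoid the
# package's matrix builders: the event simulator applies the per-dyad
# rules one random event at a time, and the 4-state model is a separate
# re-implementation of the u/m-only chain.

# --- event-level one-step simulator -----------------------------------
# Simulates n dyads starting in `state` through one division cycle:
# replace a uniformly chosen strand with u, apply maintenance / de novo
# methylation, then per-strand hydroxylation.  Returns the empirical
# distribution over the 9 states in canonical order.
simulate_one_step_events <- function(state, n, mu_m, mu_d, eta, p) {
  marks <- strsplit(state, "")[[1]]
  up <- rep(marks[1], n)
  lo <- rep(marks[2], n)
  # replication: one strand becomes unmodified
  repl_upper <- stats::runif(n) < 0.5
  up[repl_upper] <- "u"
  lo[!repl_upper] <- "u"
  # methylation: classify dyads on the post-division marks, apply all
  # gains simultaneously (one methylation round per cycle, no cascades)
  up0 <- up
  lo0 <- lo
  both_u <- up0 == "u" & lo0 == "u"
  methylate_strand <- function(u_side, other) {
    # unmethylated dyad: de novo only, independently per strand
    gain <- both_u & u_side == "u" & stats::runif(n) < mu_d
    # u strand opposite m: maintenance first, de novo as fallback
    target <- u_side == "u" & other == "m"
    gain <- gain | (target & (stats::runif(n) < mu_m | stats::runif(n) < mu_d))
    # u strand opposite h: blocked with probability p -> de novo only
    target_h <- u_side == "u" & other == "h"
    blocked <- stats::runif(n) < p
    gain | (target_h & ifelse(blocked,
      stats::runif(n) < mu_d,
      stats::runif(n) < mu_m | stats::runif(n) < mu_d
    ))
  }
  up_gain <- methylate_strand(up0, lo0)
  lo_gain <- methylate_strand(lo0, up0)
  up[up_gain] <- "m"
  lo[lo_gain] <- "m"
  # hydroxylation
  up[up == "m" & stats::runif(n) < eta] <- "h"
  lo[lo == "m" & stats::runif(n) < eta] <- "h"
  freq <- table(factor(paste0(up, lo), levels = dyad_states()))
  as.numeric(freq) / n
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# --- independent 4-state (u/m only) model -----------------------------
# States uu, um, mu, mm in that order; observables TT, TC, CT, CC.

um4_states <- c("uu", "um", "mu", "mm")

um4_division <- function() {
  matrix(c(
    1, 0, 0, 0,
    0.5, 0.5, 0, 0,
    0.5, 0, 0.5, 0,
    0, 0.5, 0.5, 0
  ), 4, 4, byrow = TRUE, dimnames = list(um4_states, um4_states))
}

um4_methylation <- function(mu_m, mu_d) {
  lam <- mu_m + mu_d - mu_m * mu_d
  matrix(c(
    (1 - mu_d)^2, (1 - mu_d) * mu_d, mu_d * (1 - mu_d), mu_d^2,
    0, 1 - lam, 0, lam,
    0, 0, 1 - lam, lam,
    0, 0, 0, 1
  ), 4, 4, byrow = TRUE, dimnames = list(um4_states, um4_states))
}

um4_emission <- function(c_prob, d_prob) {
  pT <- c(u = c_prob, m = 1 - d_prob)
  E <- matrix(0, 4, 4, dimnames = list(um4_states, c("TT", "TC", "CT", "CC")))
  for (i in 1:4) {
    s <- strsplit(um4_states[i], "")[[1]]
    E[i, ] <- c(
      pT[s[1]] * pT[s[2]], pT[s[1]] * (1 - pT[s[2]]),
      (1 - pT[s[1]]) * pT[s[2]], (1 - pT[s[1]]) * (1 - pT[s[2]])
    )
  }
  E
}

# Negative log-likelihood of the dynamics for the 4-state model on an
# observation_dataset with h-free hidden states.
um4_nll <- function(pairs, pi0_4, data, t_max) {
  days <- setdiff(data$days, 0)
  D <- um4_division()
  pis <- matrix(NA_real_, t_max + 1, 4)
  pis[1, ] <- pi0_4
  pv <- pi0_4
  for (k in seq_len(t_max)) {
    mu_m <- pairs$mu_m[1] + pairs$mu_m[2] * k
    mu_d <- pairs$mu_d[1] + pairs$mu_d[2] * k
    if (mu_m < -1e-9 || mu_m > 1 + 1e-9 || mu_d < -1e-9 || mu_d > 1 + 1e-9) {
      return(Inf)
    }
    mu_m <- min(max(mu_m, 0), 1)
    mu_d <- min(max(mu_d, 0), 1)
    pv <- as.vector((pv %*% D) %*% um4_methylation(mu_m, mu_d))
    pis[k + 1, ] <- pv
  }
  nll <- 0
  for (d in days) {
    for (tr in c("bs", "ox")) {
      n <- counts_for(data, d, tr)
      if (is.null(n)) next
      prof <- get_profile(data, d, tr)
      pred <- as.vector(pis[d * data$divisions_per_day + 1, ] %*%
        um4_emission(prof$c, prof$d))
      pos <- n > 0
      if (any(pos & pred <= 0)) {
        return(Inf)
      }
      nll <- nll - sum(n[pos] * log(pred[pos]))
    }
  }
  nll
}

# Multi-start fit of (mu_m, mu_d) intercept/slope in the 4-state model,
# mirroring the box reparameterization q = (f(1), f(t_max)) and the
# optimizer settings of the package so optima are comparable to 1e-6.
um4_fit <- function(data, pi0_4, starts, seed, t_max, factr = 1e2) {
  q_to_pairs <- function(q) {
    s1 <- (q[2] - q[1]) / (t_max - 1)
    s2 <- (q[4] - q[3]) / (t_max - 1)
    list(mu_m = c(q[1] - s1, s1), mu_d = c(q[3] - s2, s2))
  }
  obj <- function(q) {
    v <- um4_nll(q_to_pairs(q), pi0_4, data, t_max)
    if (!is.finite(v)) 1e12 else v
  }
  set.seed(seed)
  start_mat <- matrix(stats::runif(starts * 4), starts, 4)
  fits <- lapply(seq_len(starts), function(s) {
    stats::optim(start_mat[s, ], obj,
      method = "L-BFGS-B", lower = rep(0, 4),
      upper = rep(1, 4), control = list(factr = factr, maxit = 1000)
    )
  })
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]
  c(q_to_pairs(best$par), list(value = best$value))
}
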
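# Shared fixtures: small configurations and hand-built datasets.

ideal_profiles <- function() {
  list(
    bs = conversion_profile("bs", 1, 1, e = 1),
    ox = conversion_profile("ox", 1, 1, f = 1)
  )
}

default_truth_model <- function() {
  efficiency_model(
    mu_m = c(0.8, 0), mu_d = c(0.3, -0.02),
    eta = c(0.05, 0.03), p = 1
  )
}

default_truth_pi0 <- function() {
  c(
    uu = 0.06, um = 0.04, mu = 0.04, uh = 0.01, hu = 0.01,
    mm = 0.70, mh = 0.05, hm = 0.05, hh = 0.04
  )
}

# dataset with a single (day, treatment) count vector per row spec
make_dataset <- function(..., profiles = ideal_profiles(), divisions_per_day = 1) {
  rows <- list(...)
  counts <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      day = r$day, treatment = r$treatment,
      TT = r$n[1], TC = r$n[2], CT = r$n[3], CC = r$n[4]
    )
  }))
  observation_dataset(counts,
    profiles = profiles,
    divisions_per_day = divisions_per_day
  )
}

point_mass <- function(state) {
  pi0 <- stats::setNames(rep(0, 9), dyad_states())
  pi0[state] <- 1
  pi0
}
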
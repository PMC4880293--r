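test_that("day-0 likelihood matches hand-computed multinomial terms", {
  # all mass on uu, only TT observed: every term is log(1)
  ds <- make_dataset(
    list(day = 0, treatment = "bs", n = c(100, 0, 0, 0)),
    list(day = 0, treatment = "ox", n = c(100, 0, 0, 0))
  )
  expect_equal(neg_log_likelihood_initial(point_mass("uu"), ds), 0)
  # a zero-probability observation makes the likelihood vanish
  ds2 <- make_dataset(
    list(day = 0, treatment = "bs", n = c(99, 0, 0, 1)),
    list(day = 0, treatment = "ox", n = c(100, 0, 0, 0))
  )
  expect_identical(neg_log_likelihood_initial(point_mass("uu"), ds2), Inf)
  # uniform hidden states, one BS TT read: -log(1/9)
  ds3 <- make_dataset(
    list(day = 0, treatment = "bs", n = c(1, 0, 0, 0)),
    list(day = 0, treatment = "ox", n = c(0, 0, 0, 0))
  )
  expect_equal(neg_log_likelihood_initial(rep(1 / 9, 9), ds3), log(9),
    tolerance = 1e-12
  )
  expect_error(
    neg_log_likelihood_initial(
      point_mass("uu"),
      make_dataset(list(day = 1, treatment = "bs", n = c(1, 0, 0, 0)))
    ),
    "day-0"
  )
})

test_that("dynamics likelihood propagates through the fitted chain", {
  model0 <- efficiency_model(mu_m = c(0, 0), mu_d = c(0, 0), eta = c(0, 0), p = 0)
  ds <- make_dataset(
    list(day = 1, treatment = "bs", n = c(50, 0, 0, 0)),
    list(day = 3, treatment = "bs", n = c(50, 0, 0, 0)),
    list(day = 6, treatment = "ox", n = c(50, 0, 0, 0))
  )
  expect_equal(neg_log_likelihood_dynamics(model0, point_mass("uu"), ds), 0)
  ds_bad <- make_dataset(list(day = 1, treatment = "bs", n = c(49, 0, 0, 1)))
  expect_identical(
    neg_log_likelihood_dynamics(model0, point_mass("uu"), ds_bad), Inf
  )
  # at high coverage the expected-count objective equals coverage times
  # the cross-entropy and is minimized at the generating parameters
  truth <- default_truth_model()
  pi0 <- default_truth_pi0()
  N <- 1e5
  rows <- list()
  for (d in c(1, 3, 6)) {
    pi_t <- propagate(pi0, truth, d)
    for (tr in c("bs", "ox")) {
      prof <- if (tr == "bs") ideal_profiles()$bs else ideal_profiles()$ox
      rows[[length(rows) + 1]] <- list(
        day = d, treatment = tr,
        n = round(N * observable_distribution(pi_t, prof))
      )
    }
  }
  ds_exp <- do.call(make_dataset, rows)
  nll_truth <- neg_log_likelihood_dynamics(truth, pi0, ds_exp)
  cross_entropy <- 0
  for (d in c(1, 3, 6)) {
    pi_t <- propagate(pi0, truth, d)
    for (tr in c("bs", "ox")) {
      prof <- if (tr == "bs") ideal_profiles()$bs else ideal_profiles()$ox
      pred <- observable_distribution(pi_t, prof)
      n <- counts_for(ds_exp, d, tr)
      cross_entropy <- cross_entropy - sum(n * log(pred))
    }
  }
  expect_equal(nll_truth, cross_entropy, tolerance = 1e-10)
  # perturbed parameters never beat the truth on expected counts
  # (up to the rounding of the expected counts)
  for (delta in c(-0.05, 0.05)) {
    alt <- efficiency_model(
      mu_m = truth$mu_m + c(delta, 0), mu_d = truth$mu_d,
      eta = truth$eta, p = truth$p
    )
    expect_gt(neg_log_likelihood_dynamics(alt, pi0, ds_exp), nll_truth)
  }
})

test_that("likelihoods are invariant under a simultaneous strand swap", {
  set.seed(421)
  swap_counts <- function(n) n[c(1, 3, 2, 4)]
  profiles <- list(
    bs = conversion_profile("bs", 0.99, 0.97, e = 0.9),
    ox = conversion_profile("ox", 0.99, 0.97, f = 0.9)
  )
  for (rep in 1:5) {
    g <- rexp(9)
    pi0 <- g / sum(g)
    names(pi0) <- dyad_states()
    pi0_swapped <- pi0[swap_state(dyad_states())]
    names(pi0_swapped) <- dyad_states()
    n_bs <- rpois(4, 50)
    n_ox <- rpois(4, 50)
    n_bs1 <- rpois(4, 80)
    n_ox1 <- rpois(4, 80)
    ds <- make_dataset(
      list(day = 0, treatment = "bs", n = n_bs),
      list(day = 0, treatment = "ox", n = n_ox),
      list(day = 1, treatment = "bs", n = n_bs1),
      list(day = 1, treatment = "ox", n = n_ox1),
      profiles = profiles
    )
    ds_swapped <- make_dataset(
      list(day = 0, treatment = "bs", n = swap_counts(n_bs)),
      list(day = 0, treatment = "ox", n = swap_counts(n_ox)),
      list(day = 1, treatment = "bs", n = swap_counts(n_bs1)),
      list(day = 1, treatment = "ox", n = swap_counts(n_ox1)),
      profiles = profiles
    )
    expect_equal(
      neg_log_likelihood_initial(pi0, ds),
      neg_log_likelihood_initial(pi0_swapped, ds_swapped)
    )
    model <- efficiency_model(
      mu_m = runif(1), mu_d = runif(1), eta = runif(1), p = runif(1)
    )
    expect_equal(
      neg_log_likelihood_dynamics(model, pi0, ds),
      neg_log_likelihood_dynamics(model, pi0_swapped, ds_swapped)
    )
  }
})
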
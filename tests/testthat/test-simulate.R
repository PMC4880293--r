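test_that("identical seeds give identical datasets", {
  cfg <- simulation_config(coverage = 500, seed = 201)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  d3 <- generate_dataset(simulation_config(coverage = 500, seed = 202))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("hidden pools follow the propagated distribution", {
  # division-only dynamics from (hh): day 1 is all uh/hu
  cfg <- simulation_config(
    model = efficiency_model(mu_m = c(0, 0), mu_d = c(0, 0), eta = c(0, 0), p = 1),
    pi0 = point_mass("hh"), days = c(0, 1), coverage = 2000, seed = 203
  )
  set.seed(203)
  hidden <- simulate_hidden_states(cfg)
  day1 <- hidden$bs["1", ]
  expect_equal(sum(day1[c("uh", "hu")]) / sum(day1), 1)

  # large-pool frequencies track propagate() in total variation
  cfg2 <- simulation_config(days = c(0, 6), coverage = 1e5, seed = 204)
  set.seed(204)
  hidden2 <- simulate_hidden_states(cfg2)
  emp <- hidden2$ox["6", ] / sum(hidden2$ox["6", ])
  expect_lt(total_variation(emp, propagate(cfg2$pi0, cfg2$model, 6)), 0.01)
})

test_that("read emission matches the conversion channels", {
  # all-(uu) pool with ideal conversion reads TT everywhere
  cfg <- simulation_config(
    pi0 = point_mass("uu"),
    model = efficiency_model(mu_m = c(0, 0), mu_d = c(0, 0), eta = c(0, 0), p = 0),
    days = c(0, 1), coverage = 300, profiles = ideal_profiles(), seed = 205
  )
  ds <- generate_dataset(cfg)
  expect_equal(sum(ds$counts$TT), sum(ds$counts[c("TT", "TC", "CT", "CC")]))
  # all-(hh) pool: BS reads CC, oxBS reads TT
  cfg2 <- simulation_config(
    pi0 = point_mass("hh"),
    model = efficiency_model(mu_m = c(0, 0), mu_d = c(0, 0), eta = c(0, 0), p = 0),
    days = c(0), coverage = 300, profiles = ideal_profiles(), seed = 206
  )
  ds2 <- generate_dataset(cfg2)
  expect_equal(counts_for(ds2, 0, "bs")[["CC"]], 300)
  expect_equal(counts_for(ds2, 0, "ox")[["TT"]], 300)
  # imperfect 5mC retention: CC fraction near d^2
  cfg3 <- simulation_config(
    pi0 = point_mass("mm"),
    model = efficiency_model(mu_m = c(1, 0), mu_d = c(0, 0), eta = c(0, 0), p = 0),
    days = c(0), coverage = 20000,
    profiles = list(
      bs = conversion_profile("bs", 1, 0.9, e = 1),
      ox = conversion_profile("ox", 1, 0.9, f = 1)
    ), seed = 207
  )
  ds3 <- generate_dataset(cfg3)
  frac_cc <- counts_for(ds3, 0, "bs")[["CC"]] / 20000
  expect_equal(frac_cc, 0.81, tolerance = 0.02)
})

test_that("generated counts match the observable distribution in distribution", {
  cfg <- simulation_config(coverage = 10000, seed = 208)
  ds <- generate_dataset(cfg)
  for (d in cfg$days) {
    pi_t <- propagate(cfg$pi0, cfg$model, d)
    for (tr in c("bs", "ox")) {
      expected <- observable_distribution(pi_t, get_profile(ds, d, tr))
      gof <- suppressWarnings(
        chisq.test(counts_for(ds, d, tr), p = expected)
      )
      expect_gt(gof$p.value, 0.001)
    }
  }
})

test_that("zero-coverage days are excluded and per-CpG mode shares the truth", {
  cov_tab <- data.frame(
    day = rep(c(0, 1, 3), each = 2),
    treatment = rep(c("bs", "ox"), 3),
    coverage = c(500, 500, 0, 0, 500, 500)
  )
  cfg <- simulation_config(days = c(0, 1, 3), coverage = cov_tab, seed = 209)
  ds <- generate_dataset(cfg)
  expect_equal(ds$days, c(0, 3))
  cfg2 <- simulation_config(days = c(0, 1), coverage = 200, n_cpg = 3, seed = 210)
  multi <- generate_dataset(cfg2)
  expect_length(multi, 3)
  truths <- lapply(multi, attr, "ground_truth")
  expect_identical(truths[[1]], truths[[2]])
  expect_identical(truths[[1]], truths[[3]])
  expect_false(identical(multi[[1]]$counts, multi[[2]]$counts))
})
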
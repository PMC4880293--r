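test_that("division matrix dilutes marks onto the replaced strand", {
  D <- division_matrix()
  expect_equal(D["mm", c("um", "mu")], c(um = 0.5, mu = 0.5))
  expect_equal(sum(D["mm", ]), 1)
  expect_equal(D["hh", c("uh", "hu")], c(uh = 0.5, hu = 0.5))
  expect_equal(D["uu", "uu"], 1)
  expect_equal(D["hm", c("hu", "um")], c(hu = 0.5, um = 0.5))
  expect_equal(rowSums(D), setNames(rep(1, 9), dyad_states()))
})

test_that("methylation matrix combines maintenance and de novo as lambda", {
  M <- methylation_matrix(0.5, 0.2, 0)
  # lambda = 0.5 + 0.2 - 0.1 = 0.6 on hemimethylated dyads
  expect_equal(M["um", c("mm", "um")], c(mm = 0.6, um = 0.4))
  M2 <- methylation_matrix(0, 0.5, 0)
  expect_equal(
    M2["uu", c("mm", "um", "mu", "uu")],
    c(mm = 0.25, um = 0.25, mu = 0.25, uu = 0.25)
  )
  # p = 1 blocks maintenance at hemi-hydroxylated dyads: de novo only
  M3 <- methylation_matrix(0.9, 0.3, 1)
  expect_equal(M3["hu", c("hm", "hu")], c(hm = 0.3, hu = 0.7))
  # hydroxyl-bearing modified dyads are untouched by the Dnmts
  for (s in c("mh", "hm", "hh", "mm")) {
    expect_equal(M3[s, s], 1, info = s)
  }
  expect_error(methylation_matrix(1.2, 0, 0), "probability")
})

test_that("hydroxylation matrix oxidizes each methylated strand independently", {
  expect_equal(hydroxylation_matrix(0), diag(9), ignore_attr = TRUE)
  H <- hydroxylation_matrix(0.5)
  expect_equal(
    H["mm", c("hh", "hm", "mh", "mm")],
    c(hh = 0.25, hm = 0.25, mh = 0.25, mm = 0.25)
  )
  H2 <- hydroxylation_matrix(0.1)
  expect_equal(H2["um", c("uh", "um")], c(uh = 0.1, um = 0.9))
  expect_error(hydroxylation_matrix(-0.1), "probability")
})

test_that("composite transition matrix is D M H with stochastic rows", {
  # perfect maintenance restores full methylation every division
  m1 <- efficiency_model(mu_m = c(1, 0), mu_d = c(0, 0), eta = c(0, 0), p = 0)
  expect_equal(transition_matrix(1, m1)["mm", "mm"], 1)
  # no enzymes: replication dilution only
  m0 <- efficiency_model()
  P0 <- transition_matrix(3, m0)
  expect_equal(P0["mm", c("um", "mu")], c(um = 0.5, mu = 0.5))
  # certain de novo methylates both strands within one cycle
  m2 <- efficiency_model(mu_m = c(0, 0), mu_d = c(1, 0), eta = c(0, 0), p = 0)
  expect_equal(transition_matrix(1, m2)["uu", "mm"], 1)
  # out-of-range efficiency at the requested division errors
  m3 <- efficiency_model(mu_d = c(0.5, 0.2))
  expect_error(transition_matrix(4, m3), "outside")
})

test_that("transition structure is row-stochastic and strand-swap symmetric", {
  set.seed(401)
  swap <- swap_state(seq_len(9))
  for (rep in 1:10) {
    pars <- runif(4)
    mats <- list(
      division_matrix(),
      methylation_matrix(pars[1], pars[2], pars[4]),
      hydroxylation_matrix(pars[3]),
      transition_matrix(1, efficiency_model(
        mu_m = pars[1], mu_d = pars[2], eta = pars[3], p = pars[4]
      ))
    )
    for (A in mats) {
      expect_true(all(A >= 0 & A <= 1))
      expect_equal(unname(rowSums(A)), rep(1, 9), tolerance = 1e-12)
      expect_equal(unname(A), unname(A[swap, swap]))
    }
  }
})

test_that("hydroxylated states are unreachable without hydroxylation", {
  set.seed(402)
  h_states <- grepl("h", dyad_states())
  model <- efficiency_model(mu_m = c(0.7, 0.01), mu_d = c(0.2, -0.01), eta = c(0, 0), p = 0.5)
  pi0 <- c(uu = 0.2, um = 0.1, mu = 0.1, uh = 0, hu = 0, mm = 0.6, mh = 0, hm = 0, hh = 0)
  for (t in c(1, 3, 6)) {
    expect_equal(sum(propagate(pi0, model, t)[h_states]), 0)
  }
})

test_that("passive dilution drains all modification toward uu", {
  model <- efficiency_model() # all efficiencies zero
  pi0 <- default_truth_pi0()
  pi_far <- propagate(pi0, model, 40)
  expect_gt(pi_far["uu"], 1 - 1e-9)
})

test_that("propagation preserves mass and honours the halving of 5hmC", {
  model <- efficiency_model(mu_m = c(0, 0), mu_d = c(0, 0), eta = c(0, 0), p = 1)
  expect_equal(propagate(point_mass("hh"), model, 0), point_mass("hh"))
  pi1 <- propagate(point_mass("hh"), model, 1)
  expect_equal(pi1[c("uh", "hu")], c(uh = 0.5, hu = 0.5))
  set.seed(403)
  for (rep in 1:5) {
    pars <- runif(4)
    m <- efficiency_model(mu_m = pars[1], mu_d = pars[2], eta = pars[3], p = pars[4])
    g <- rexp(9)
    expect_equal(sum(propagate(g / sum(g), m, 4)), 1, tolerance = 1e-12)
  }
})

test_that("one-step event simulation matches every transition-matrix row", {
  set.seed(404)
  n <- 20000
  pars <- runif(4)
  model <- efficiency_model(mu_m = pars[1], mu_d = pars[2], eta = pars[3], p = pars[4])
  P <- transition_matrix(1, model)
  for (s in dyad_states()) {
    emp <- simulate_one_step_events(s, n, pars[1], pars[2], pars[3], pars[4])
    expect_lt(total_variation(emp, P[s, ]), 0.02)
  }
})
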
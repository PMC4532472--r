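test_that("three-species builder wires the chain and its abridgment together", {
  sys <- build_three_species(1, 100, 1)
  expect_equal(sys$rate, 1 * 1 / (1 + 100), tolerance = 1e-12)
  expect_true(validity_check(sys$chain)$valid)
  expect_false(validity_check(build_three_species(1, 1, 1)$chain)$valid)
  expect_true(validity_check(build_three_species(100, 1, 1)$chain)$valid)
  # the reduced network fires S1 -> S3 at the abridged rate
  expect_equal(propensities(sys$reduced, c(S1 = 1, S3 = 0)), sys$rate)
})

test_that("the full switch conserves total Cdh1 along trajectories", {
  p <- switch_params(k = 0.5)
  net <- build_bistable_switch(p)
  traj <- simulate_ssa(net, switch_init_state(p), t_end = 50, seed = 13)
  forms <- paste0("Cdh1P", 0:9)
  totals <- rowSums(as.matrix(traj[, forms]))
  expect_true(all(totals == p$m))
})

test_that("freezing Clb2 reduces the switch to a uniform-rate chain", {
  p <- switch_params(k = 0.05)
  clb2 <- 12
  ch <- switch_frozen_chain(p, clb2)
  expect_equal(ch$forward, rep(p$k * clb2, 9))
  expect_equal(ch$backward, rep(p$k * p$kp, 9))
  expect_identical(ch$particles, p$m)
  # full-model phosphorylation propensities at frozen Clb2 equal the chain's
  net <- build_bistable_switch(p)
  st <- switch_init_state(p, clb2)
  a <- propensities(net, st)
  expect_equal(a[1], p$k * clb2 * p$m)        # all particles at P0
  expect_equal(a[2], 0)                        # nothing to dephosphorylate
  # the frozen chain passes the full spectral cross-checks
  expect_s3_class(spectral_report(ch), "spectral_report")
})

test_that("uniform occupancy at Clb2 = kp gives mean degradation weight 5.5", {
  p <- switch_params(k = 1)
  expect_equal(switch_qss_weight(p, p$kp), 5.5, tolerance = 1e-12)
  expect_equal(equilibrium_distribution(switch_frozen_chain(p, p$kp)),
               rep(0.1, 10))
  # degradation propensity at uniform Cdh1 occupancy: ka * m * 5.5 per Clb2
  net <- build_bistable_switch(p)
  st <- c(setNames(rep(1, 10), paste0("Cdh1P", 0:9)), Clb2 = 8)
  a <- propensities(net, st)
  expect_equal(a[length(a)], p$ka * 55 * 8, tolerance = 1e-12)
})

test_that("reduced switch propensity follows the truncated-geometric weight", {
  p <- switch_params(k = 1)
  net <- build_reduced_switch(p)
  a_at <- function(c) propensities(net, c(Clb2 = c))[2]
  expect_equal(a_at(8), 5.5 * p$ka * p$m * 8, tolerance = 1e-12)
  expect_equal(a_at(0), 0)
  # geometric limits: weight -> 1 as Clb2 grows, -> levels as Clb2 -> 0+
  expect_equal(switch_qss_weight(p, 1e7), 1, tolerance = 1e-5)
  expect_equal(switch_qss_weight(p, 1e-7), 10, tolerance = 1e-5)
  # cross-check the closed form against the equilibrium linear solve
  for (clb2 in c(1, 5, 8, 20)) {
    pi <- equilibrium_distribution(switch_frozen_chain(p, clb2))
    expect_equal(switch_qss_weight(p, clb2), sum((10:1) * pi),
                 tolerance = 1e-10)
  }
})

test_that("enzyme chain: E conserved by chain steps, chain untouched by turnover", {
  net <- build_enzyme_chain(k0 = 2, e_synthesis = 0.5, ku = 0.01, u = 2,
                            n = 4)
  nu <- vapply(net$reactions, function(r) r$change, integer(5))
  chain_cols <- seq_len(2 * 3)              # forward/backward pairs
  expect_true(all(nu[5, chain_cols] == 0))  # E untouched by chain steps
  expect_true(all(colSums(nu[1:4, ]) [c(7, 8)] == 0)) # S total kept by E rxns
  expect_true(all(nu[1:4, 7:8] == 0))
  # with E frozen the chain is the uniform chain with rates k0 * E
  st <- c(S1 = 1, S2 = 0, S3 = 0, S4 = 0, E = 6)
  a <- propensities(net, st)
  expect_equal(a[1], 2 * 6 * 1)
  # frozen-chain equilibrium is uniform, so E decays at ku * m / n per enzyme
  ch <- chain_spec(rep(2 * 6, 3), rep(2 * 6, 3))
  expect_equal(equilibrium_distribution(ch), rep(0.25, 4))
  traj <- simulate_ssa(net, st, t_end = 20, seed = 17)
  expect_true(all(rowSums(as.matrix(traj[, paste0("S", 1:4)])) == 1))
})

test_that("relaxation curve scales as 1/k and flags the Clb2 = 0 chain", {
  p1 <- switch_params(k = 0.5)
  p2 <- switch_params(k = 5)
  c1 <- relaxation_vs_firing_curve(p1, c(0, 5, 15))
  c2 <- relaxation_vs_firing_curve(p2, c(0, 5, 15))
  expect_equal(c1$t_relax, 10 * c2$t_relax, tolerance = 1e-10)
  expect_equal(c1$slow_interval, c2$slow_interval)   # k-independent
  expect_true(c1$chain_reducible[1])
  expect_false(any(c1$chain_reducible[-1]))
  # the qss variant uses the equilibrium weight instead of the maximum
  cq <- relaxation_vs_firing_curve(p1, 5, interval = "qss")
  expect_gt(cq$slow_interval, c1$slow_interval[2])
})
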
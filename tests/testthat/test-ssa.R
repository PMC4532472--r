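test_that("pure birth process fires at the Poisson rate", {
  net <- reaction_network("S", list(
    reaction(1L, propensity_mass_action(1), "birth")))
  counts <- vapply(1:200, function(s) {
    traj <- simulate_ssa(net, c(S = 0), t_end = 20, seed = s)
    unname(attr(traj, "final_state")["S"])
  }, numeric(1))
  # mean count over replicates ~ Poisson(20): 3 standard errors
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 200))
})

test_that("single-particle decay stops at an exponential time", {
  c_rate <- 0.5
  net <- reaction_network("S", list(
    reaction(-1L, propensity_mass_action(c_rate, c(S = 1)), "decay")))
  times <- vapply(1:2000, function(s) {
    traj <- simulate_ssa(net, c(S = 1), t_end = 1e6, seed = s,
                         stop_predicate = list(species = "S", value = 0,
                                               op = "<="),
                         record = "none")
    expect_true(attr(traj, "stopped"))
    attr(traj, "stop_time")
  }, numeric(1))
  expect_lt(abs(mean(times) - 1 / c_rate), 3 * sd(times) / sqrt(2000))
})

test_that("stop predicate halts at first passage; mean matches the survival integral", {
  chain <- three_species_chain(1, 1, 1)
  net <- chain_to_network(chain)
  times <- vapply(1:1500, function(s) {
    traj <- simulate_ssa(net, c(1, 0, 0), t_end = 1e5, seed = s,
                         stop_predicate = list(species = "S3", value = 1),
                         record = "none")
    attr(traj, "stop_time")
  }, numeric(1))
  expect_lt(abs(mean(times) - mean_exit_time_oracle(chain)),
            3 * sd(times) / sqrt(1500))
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  net <- birth_death_network(2, 0.3)
  a <- simulate_ssa(net, c(S = 0), t_end = 100, seed = 123)
  b <- simulate_ssa(net, c(S = 0), t_end = 100, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_ssa(net, c(S = 0), t_end = 100, seed = 124)
  expect_false(identical(nrow(a), nrow(c)) &&
                 isTRUE(all.equal(as.data.frame(a), as.data.frame(c))))
})

test_that("a frozen system yields a constant trajectory to the horizon", {
  net <- reaction_network("S", list(
    reaction(-1L, propensity_mass_action(1, c(S = 1)), "decay")))
  traj <- simulate_ssa(net, c(S = 0), t_end = 10, seed = 1)
  expect_equal(attr(traj, "final_time"), 10)
  expect_equal(unname(attr(traj, "final_state")), 0)
  d <- time_fraction_distribution(traj, "S")
  expect_equal(d$copies, 0L)
  expect_equal(d$prob, 1)
})

test_that("negative custom propensities fail loudly, naming the reaction", {
  net <- reaction_network("S", list(
    reaction(1L, propensity_function(function(x) 0.5 - x[["S"]]), "bad")))
  expect_error(simulate_ssa(net, c(S = 0), t_end = 100, seed = 1),
               "propensity.*reaction 1")
})

test_that("time-fraction distributions integrate the piecewise-constant path", {
  # hand-built two-interval path: x = 0 for 2 time units, then 1 for 2
  net <- reaction_network("S", list(
    reaction(1L, propensity_function(function(x) if (x[["S"]] == 0) 1 else 0),
             "up")))
  # use an explicit trajectory instead: simulate then override is brittle;
  # instead verify on a degenerate two-state flip with known holding times
  # via direct computation on recorded jumps
  traj <- simulate_ssa(net, c(S = 0), t_end = 4, seed = 2)
  d <- time_fraction_distribution(traj, "S", burn_in = 0)
  t_jump <- traj$time[2]
  expect_equal(d$prob[d$copies == 0], t_jump / 4)
  expect_equal(d$prob[d$copies == 1], 1 - t_jump / 4)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("burn-in removes the early window from the estimate", {
  net <- birth_death_network(5, 1)
  traj <- simulate_ssa(net, c(S = 0), t_end = 500, seed = 9)
  d0 <- time_fraction_distribution(traj, "S", burn_in = 0)
  d1 <- time_fraction_distribution(traj, "S", burn_in = 50)
  expect_equal(sum(d1$prob), 1, tolerance = 1e-12)
  # dropping the ramp-up from zero shifts mass upward
  expect_gt(mean(d1), mean(d0))
  expect_error(time_fraction_distribution(traj, "S", burn_in = 500),
               "burn")
})

test_that("online occupancy equals the exact jump-record integration", {
  net <- birth_death_network(3, 0.5)
  full <- simulate_ssa(net, c(S = 0), t_end = 300, seed = 4, burn_in = 30)
  thin <- simulate_ssa(net, c(S = 0), t_end = 300, seed = 4, burn_in = 30,
                       record = "thin", thin_dt = 10)
  d_full <- time_fraction_distribution(full, "S", burn_in = 30)
  d_thin <- time_fraction_distribution(thin, "S")
  joined <- dplyr::full_join(d_full, d_thin, by = "copies")
  expect_equal(joined$prob.x, joined$prob.y, tolerance = 1e-12)
})

test_that("birth-death occupancy converges to the Poisson stationary law", {
  a <- 4; b <- 1
  net <- birth_death_network(a, b)
  traj <- simulate_ssa(net, c(S = 0), t_end = 4e4, seed = 6, record = "none",
                       burn_in = 500)
  d <- time_fraction_distribution(traj, "S")
  pois <- stats::dpois(d$copies, a / b)
  expect_lt(sum(abs(d$prob - pois)), 0.05)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("SSA occupancy matches the brute-force CME stationary distribution", {
  # one particle hopping on a 3-state chain: enumerable state space
  ch <- chain_spec(c(2, 1), c(1, 3), exit_rate = 0)
  net <- chain_to_network(ch)
  pi <- equilibrium_distribution(ch)   # null vector of the 3x3 generator
  traj <- simulate_ssa(net, c(1, 0, 0, 0), t_end = 2e4, seed = 8,
                       record = "none", burn_in = 200)
  occ <- vapply(paste0("S", 1:3), function(s) {
    d <- time_fraction_distribution(traj, s)
    sum(d$prob[d$copies == 1])
  }, numeric(1))
  expect_lt(max(abs(occ - pi)), 0.02)
})

test_that("structured propensity kinds match an R-closure re-implementation", {
  # express the same models through arbitrary R-function propensities and
  # check the compiled structured kinds produce identical trajectories
  p <- switch_params(k = 0.5)
  as_rfun <- function(net) {
    reaction_network(net$species, lapply(net$reactions, function(r) {
      reaction(r$change,
               propensity_function(local({
                 rr <- r
                 function(x) propensities(reaction_network(net$species,
                                                           list(rr)), x)
               })),
               r$name)
    }))
  }
  cases <- list(
    list(net = build_reduced_switch(p), init = c(Clb2 = 7), t_end = 200),
    list(net = build_bistable_switch(p), init = switch_init_state(p),
         t_end = 5)
  )
  for (cs in cases) {
    fast <- simulate_ssa(cs$net, cs$init, t_end = cs$t_end, seed = 77)
    slow <- simulate_ssa(as_rfun(cs$net), cs$init, t_end = cs$t_end,
                         seed = 77)
    expect_equal(as.data.frame(fast), as.data.frame(slow), tolerance = 1e-12)
  }
})

test_that("trajectory round-trips through the TSV writer", {
  net <- birth_death_network(1, 0.2)
  traj <- simulate_ssa(net, c(S = 0), t_end = 50, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj), ignore_attr = TRUE)
  expect_equal(attr(back, "seed"), 5L)
  expect_equal(attr(back, "final_time"), 50)
  expect_equal(attr(back, "n_steps"), attr(traj, "n_steps"))
})
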
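test_that("generator A has the tridiagonal structure with the exit on its diagonal", {
  # two-state chain S1 <-> S2 -> S3 with rates c1, c2, c3
  A <- build_generator_A(three_species_chain(2, 3, 5))
  expect_equal(A, matrix(c(-2, 2, 3, -(3 + 5)), 2, 2))

  A3 <- build_generator_A(chain_spec(c(1, 1), c(1, 1), exit_rate = 1))
  expect_equal(A3, matrix(c(-1, 1, 0, 1, -2, 1, 0, 1, -2), 3, 3))

  # conservation: all columns sum to zero except the exit column
  ch <- chain_spec(c(0.3, 2, 7), c(5, 0.1, 1), exit_rate = 0.4,
                   exit_index = 2)
  cs <- colSums(build_generator_A(ch))
  expect_equal(cs, c(0, -0.4, 0, 0))
})

test_that("generator B is conservative and differs from A by a rank-one exit term", {
  expect_equal(build_generator_B(chain_spec(1, 1, exit_rate = 3)),
               matrix(c(-1, 1, 1, -1), 2, 2))
  for (ch in generate_random_chains(10, seed = 11)) {
    B <- build_generator_B(ch)
    expect_equal(colSums(B), rep(0, ch$n))
    E <- build_generator_A(ch) - B
    expect_equal(sum(E != 0), 1L)
    expect_equal(E[ch$exit_index, ch$exit_index], -ch$exit_rate)
  }
})

test_that("relaxation time matches closed forms and scales inversely with rates", {
  expect_equal(relaxation_time(chain_spec(2, 3, exit_rate = 0.1)), 1 / 5)
  ch <- chain_spec(c(1, 4), c(2, 8), exit_rate = 0.3)
  expect_equal(relaxation_time(scale_chain(ch, 7)), relaxation_time(ch) / 7)
  # uniform chain against the analytic cosine spectrum
  for (clb2 in c(1, 8, 20)) {
    f <- 5 * clb2; b <- 5 * 8
    ch10 <- chain_spec(rep(f, 9), rep(b, 9), exit_rate = 0)
    gap <- abs(uniform_fast_spectrum(f, b, 10)[9])
    expect_equal(relaxation_time(ch10), 1 / gap, tolerance = 1e-10)
  }
  expect_equal(relaxation_time(chain_spec(n = 1, exit_rate = 5)), 0)
  expect_error(relaxation_time(chain_spec(c(0, 1), c(0, 1), 0.1)),
               "disconnected")
})

test_that("equilibrium from the linear solve obeys detailed balance", {
  expect_equal(equilibrium_distribution(chain_spec(c(1, 1), c(1, 1), 0)),
               rep(1 / 3, 3))
  for (ch in generate_random_chains(12, seed = 3)) {
    pi <- equilibrium_distribution(ch)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi >= 0))
    expect_lt(max(abs(build_generator_B(ch) %*% pi)), 1e-9 *
                max(abs(build_generator_B(ch))))
    expect_equal(pi, detailed_balance_equilibrium(ch), tolerance = 1e-10)
  }
  # frozen phosphorylation chain: truncated geometric with ratio Clb2/kp
  ch <- chain_spec(rep(0.05 * 20, 9), rep(0.05 * 8, 9), 0)
  pi <- equilibrium_distribution(ch)
  expect_equal(pi[-1] / pi[-10], rep(20 / 8, 9), tolerance = 1e-10)
  expect_error(equilibrium_distribution(chain_spec(c(1, 0), c(1, 1), 0.1)),
               "reducible")
})

test_that("reduced rate: two-state closed form and the small-rho limit", {
  c1 <- 1; c2 <- 100; c3 <- 1
  rr <- reduced_rate(three_species_chain(c1, c2, c3))
  expect_equal(abs(rr$gamma), c1 * c3 / (c1 + c2), tolerance = 1e-12)
  expect_equal(rr$c_m, rr$c_single)

  # gamma converges to lambda_n as the exit slows down
  base <- chain_spec(c(2, 5, 1), c(3, 1, 4), exit_rate = 1)
  gaps <- vapply(10^-(1:4), function(fn) {
    reduced_rate(chain_spec(base$forward, base$backward, fn))$rel_gap
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-4)

  # O(rho) error bound on a fixture suite pinned at rho = 1e-3; moderate
  # rate heterogeneity keeps |lambda_n| resolvable by the dense eigensolver
  chains <- generate_random_chains(20, rho_target = 1e-3, seed = 5,
                                   n_range = c(2L, 8L),
                                   rate_log_range = c(-0.5, 0.5))
  for (ch in chains) {
    rho <- validity_check(ch)$rho
    expect_lte(reduced_rate(ch)$rel_gap, 10 * rho)
  }
})

test_that("validity check flags fast-exit chains and passes slow-exit ones", {
  expect_equal(validity_check(chain_spec(1, 1, exit_rate = 0))$rho, 0)
  # two-state chain: rho = c3 / (c1 + c2)
  expect_equal(validity_check(three_species_chain(1, 100, 1))$rho, 1 / 101)
  expect_true(validity_check(three_species_chain(1, 100, 1))$valid)
  expect_true(validity_check(three_species_chain(100, 1, 1))$valid)
  expect_false(validity_check(three_species_chain(1, 1, 1))$valid)
  expect_equal(validity_check(three_species_chain(1, 1, 1))$rho, 0.5)
})

test_that("spectral report cross-checks eigenvalue interlacing on random chains", {
  # analytic spectrum of the symmetric two-state chain with unit exit
  rep2 <- spectral_report(chain_spec(1, 1, exit_rate = 1))
  expect_equal(sort(rep2$eigenvalues_A),
               sort(Re(polyroot(c(1, 3, 1)))), tolerance = 1e-10)

  for (ch in generate_random_chains(15, seed = 9)) {
    rep <- spectral_report(ch)
    d <- rep$eigenvalues_B - rep$eigenvalues_A
    tol <- 1e-8 * max(abs(rep$eigenvalues_A))
    expect_true(all(d >= -tol & d <= ch$exit_rate + tol))
    expect_true(all(rep$eigenvalues_A < tol))
    expect_lte(abs(rep$eigenvalues_A[ch$n]), ch$exit_rate + tol)
    expect_equal(sum(rep$equilibrium), 1, tolerance = 1e-12)
    expect_equal(rep$rho, ch$exit_rate * rep$t_relax)
  }
})

test_that("tidy and glance expose the report as tibbles", {
  rep <- spectral_report(chain_spec(c(1, 2), c(2, 1), exit_rate = 0.05))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 3L)
  expect_equal(td$shift, td$eigenvalue_B - td$eigenvalue_A)
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$c_m, rep$c_m)
  expect_true(gl$valid)
})
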
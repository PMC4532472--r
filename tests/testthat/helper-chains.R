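# shared fixtures and independent oracles for the chain analysis tests

# closed-form spectrum of the conservative uniform birth-death generator:
# lambda_j = -(f + b) + 2 sqrt(f b) cos(j pi / n), j = 0 .. n-1
uniform_fast_spectrum <- function(f, b, n) {
  sort(-(f + b) + 2 * sqrt(f * b) * cos(seq_len(n - 1) * pi / n))
}

# detailed-balance closed form for the fast-chain equilibrium
detailed_balance_equilibrium <- function(chain) {
  w <- cumprod(c(1, chain$forward / chain$backward))
  w / sum(w)
}

# mean exit time starting from state 1: -1' A^{-1} e1 (survival integral)
mean_exit_time_oracle <- function(chain) {
  A <- build_generator_A(chain)
  e1 <- c(1, rep(0, chain$n - 1))
  -sum(solve(A, e1))
}

# survival by direct matrix exponential, independent of the eigen-expansion
survival_expm_oracle <- function(chain, t_grid, init_index = 1) {
  A <- build_generator_A(chain)
  e1 <- rep(0, chain$n); e1[init_index] <- 1
  vapply(t_grid, function(t)
    sum(as.matrix(Matrix::expm(Matrix::Matrix(A * t))) %*% e1), numeric(1))
}

three_species_chain <- function(c1 = 1, c2 = 1, c3 = 1)
  chain_spec(forward = c1, backward = c2, exit_rate = c3)

birth_death_network <- function(birth, death) {
  reaction_network("S", list(
    reaction(1L, propensity_mass_action(birth), "birth"),
    reaction(-1L, propensity_mass_action(death, c(S = 1)), "death")
  ))
}
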
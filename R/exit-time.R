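#' Analytic survival function of the first exit time
#'
#' For one particle started in state `init_index`, the probability that it
#' has not yet exited by time `t` is `1' exp(A t) e_init`, where `A` is the
#' chain generator with the exit reaction included. Evaluated through the
#' eigen-expansion `P(t) = sum_i c_i exp(lambda_i t) xi_i` when the
#' eigenvector matrix is well-conditioned (condition number below 1e8), and
#' through a scaling-and-squaring matrix exponential otherwise; the two paths
#' agree to solver precision on diagonalizable problems.
#'
#' @param chain A [chain_spec()].
#' @param t_grid Increasing time grid starting at 0.
#' @param init_index Starting state (default 1).
#' @return A tibble of class `survival_curve` with columns `time` and
#'   `survival` (non-increasing, `survival[1] = 1`).
#' @examples
#' survival_function(chain_spec(1, 1, exit_rate = 1), seq(0, 5, 0.5))
#' @export
survival_function <- function(chain, t_grid, init_index = 1L) {
  stopifnot(inherits(chain, "chain_spec"), length(t_grid) >= 1,
            t_grid[1] == 0, !is.unsorted(t_grid))
  n <- chain$n
  stopifnot(init_index >= 1, init_index <= n)
  A <- build_generator_A(chain)
  e1 <- rep(0, n); e1[init_index] <- 1
  ee <- generator_eigen(A, vectors = TRUE)
  V <- ee$vectors
  surv <- NULL
  if (n == 1L || kappa(V, exact = TRUE) < 1e8) {
    cvec <- solve(V, e1)
    colmass <- colSums(V) * cvec
    surv <- vapply(t_grid, function(t) sum(colmass * exp(ee$values * t)),
                   numeric(1))
  } else {
    surv <- vapply(t_grid, function(t) {
      sum(as.matrix(Matrix::expm(Matrix::Matrix(A * t))) %*% e1)
    }, numeric(1))
  }
  surv <- pmin(pmax(surv, 0), 1)
  new_survival_curve(tibble::tibble(time = as.numeric(t_grid),
                                    survival = surv))
}

new_survival_curve <- function(tbl) {
  class(tbl) <- c("survival_curve", class(tbl))
  tbl
}

#' Worst-case deviation of the exit time from exponentiality
#'
#' The abridgment replaces the exit-time distribution by the exponential with
#' rate `|lambda_n|` (the dominant eigenvalue of the full generator). This
#' diagnostic returns `sup_t |S(t) - exp(lambda_n t)|` over
#' `t` in `[0, t_max_multiples / |lambda_n|]`, evaluated on a dense grid. A
#' small value certifies that the dominant mode alone describes the exit, the
#' condition under which the reduction is sound.
#'
#' @inheritParams survival_function
#' @param t_max_multiples Horizon in units of the mean exit time (default 8).
#' @param grid_points Grid resolution (default 2001).
#' @return A single number in `[0, 1]`.
#' @examples
#' exponential_deviation(chain_spec(100, 100, exit_rate = 0.1))
#' @export
exponential_deviation <- function(chain, t_max_multiples = 8,
                                  grid_points = 2001L, init_index = 1L) {
  stopifnot(inherits(chain, "chain_spec"), t_max_multiples > 0)
  if (chain$n == 1L) return(0)
  lam <- generator_eigen(build_generator_A(chain))$values[chain$n]
  if (lam == 0) return(0)
  tg <- seq(0, t_max_multiples / abs(lam), length.out = grid_points)
  sc <- survival_function(chain, tg, init_index)
  max(abs(sc$survival - exp(lam * tg)))
}

#' Survival of the earliest of m independent exit times
#'
#' With `m` independent particles the first exit is the minimum of `m` i.i.d.
#' exit times, so its survival is the single-particle survival raised to the
#' m-th power; in the exponential regime this is the exponential with rate
#' `m |lambda_n|`.
#'
#' @param single A [survival_function()] curve.
#' @param m Number of particles (>= 1).
#' @return A `survival_curve` tibble.
#' @export
m_particle_survival <- function(single, m) {
  stopifnot(inherits(single, "survival_curve"), m >= 1)
  new_survival_curve(dplyr::mutate(tibble::as_tibble(single),
                                   survival = .data$survival^m))
}

#' Empirical first-exit times by stochastic simulation
#'
#' Simulates one particle on the chain (started in state 1) with the direct
#' method and records the first time it becomes the absorbing species, once
#' per replicate. Replicate seeds are derived deterministically from `seed`.
#'
#' @inheritParams survival_function
#' @param replicates Number of independent exit times.
#' @param seed Integer seed.
#' @return A tibble with columns `replicate` and `exit_time`.
#' @examples
#' empirical_exit_times(chain_spec(n = 1, exit_rate = 2), 100, seed = 1)
#' @export
empirical_exit_times <- function(chain, replicates, seed) {
  stopifnot(inherits(chain, "chain_spec"), replicates >= 1)
  net <- chain_to_network(chain, particles = 1L)
  n <- chain$n
  init <- c(1L, rep(0L, n))
  absorb <- paste0("S", n + 1L)
  # generous horizon; essentially all mass exits within 1e6 mean exit times
  mean_scale <- if (chain$exit_rate > 0) {
    rr <- reduced_rate(chain)
    if (rr$c_single > 0) 1 / rr$c_single else 1
  } else stop("exit_rate must be positive to observe an exit", call. = FALSE)
  t_end <- 1e6 * mean_scale
  times <- vapply(seq_len(replicates), function(i) {
    traj <- simulate_ssa(net, init, t_end = t_end,
                         seed = (as.integer(seed) + i - 1L) %% .Machine$integer.max,
                         stop_predicate = list(species = absorb, value = 1),
                         record = "none")
    if (!attr(traj, "stopped"))
      stop("particle failed to exit within ", t_end, " time units",
           call. = FALSE)
    attr(traj, "stop_time")
  }, numeric(1))
  tibble::tibble(replicate = seq_len(replicates), exit_time = times)
}

#' Expand a chain specification into a reaction network
#'
#' Species are `S1 ... Sn` plus the absorbing `S(n+1)`; reactions are the
#' reversible nearest-neighbour steps (mass action, one particle moving at a
#' time) and the slow exit from the exit state.
#'
#' @param chain A [chain_spec()].
#' @param particles Total particles placed in the network's initial state by
#'   the caller; stored for reference only.
#' @return A [reaction_network()].
#' @export
chain_to_network <- function(chain, particles = chain$particles) {
  n <- chain$n
  sp <- paste0("S", seq_len(n + 1L))
  N <- n + 1L
  unit <- function(i, j) {
    ch <- rep(0L, N); ch[i] <- -1L; ch[j] <- 1L; ch
  }
  reactions <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      reactions <- c(reactions, list(
        reaction(unit(i, i + 1L),
                 propensity_mass_action(chain$forward[i],
                                        stats::setNames(1L, sp[i])),
                 paste0("forward_", i)),
        reaction(unit(i + 1L, i),
                 propensity_mass_action(chain$backward[i],
                                        stats::setNames(1L, sp[i + 1L])),
                 paste0("backward_", i))
      ))
    }
  }
  u <- chain$exit_index
  reactions <- c(reactions, list(
    reaction(unit(u, N),
             propensity_mass_action(chain$exit_rate,
                                    stats::setNames(1L, sp[u])),
             "exit")))
  reaction_network(sp, reactions)
}
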
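#' Specify a reversible linear chain with a slow exit reaction
#'
#' A chain `S1 <-> S2 <-> ... <-> Sn -> S(n+1)` where the reversible steps are
#' fast and the exit reaction is slow. `forward[i]` is the left-to-right rate
#' of step `Si -> S(i+1)` and `backward[i]` the rate of `S(i+1) -> Si`. The
#' exit reaction fires from state `exit_index` (by default the last state)
#' with rate constant `exit_rate`, converting that particle to the absorbing
#' species `S(n+1)`. `particles` is the number of independent particles moving
#' on the chain; it only scales the reduced rate.
#'
#' @param forward,backward Non-negative rate vectors of length `n - 1`.
#' @param exit_rate Non-negative slow exit rate constant.
#' @param exit_index State the exit reaction fires from (1..n); default `n`.
#' @param particles Number of particles on the chain (default 1).
#' @param n Number of chain states; only needed for the degenerate single-state
#'   chain (`n = 1`, empty `forward`/`backward`), otherwise inferred.
#'
#' @return An object of class `chain_spec`.
#' @examples
#' chain_spec(forward = 1, backward = 2, exit_rate = 0.01)
#' @export
chain_spec <- function(forward = numeric(), backward = numeric(),
                       exit_rate = 0, exit_index = NULL, particles = 1L,
                       n = NULL) {
  forward <- as.numeric(forward)
  backward <- as.numeric(backward)
  if (is.null(n)) n <- length(forward) + 1L
  n <- as.integer(n)
  if (n < 1L) stop("chain needs at least one state", call. = FALSE)
  if (length(forward) != n - 1L || length(backward) != n - 1L)
    stop("forward/backward must have length n - 1 = ", n - 1L, call. = FALSE)
  rates <- c(forward, backward, exit_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative", call. = FALSE)
  if (is.null(exit_index)) exit_index <- n
  exit_index <- as.integer(exit_index)
  if (exit_index < 1L || exit_index > n)
    stop("exit_index must lie in 1..n", call. = FALSE)
  particles <- as.integer(particles)
  if (particles < 1L) stop("particles must be >= 1", call. = FALSE)
  structure(
    list(n = n, forward = forward, backward = backward,
         exit_rate = as.numeric(exit_rate), exit_index = exit_index,
         particles = particles),
    class = "chain_spec"
  )
}

#' @export
print.chain_spec <- function(x, ...) {
  cat("<chain_spec> ", x$n, " states, ", x$particles, " particle(s)\n", sep = "")
  if (x$n > 1L) {
    cat("  forward:  ", paste(signif(x$forward, 4), collapse = " "), "\n")
    cat("  backward: ", paste(signif(x$backward, 4), collapse = " "), "\n")
  }
  cat("  exit: rate ", signif(x$exit_rate, 4), " from state ", x$exit_index,
      "\n", sep = "")
  invisible(x)
}

is_irreducible <- function(chain) {
  chain$n == 1L || all(chain$forward > 0 & chain$backward > 0)
}

#' Rescale every rate of a chain by a common factor
#'
#' Multiplying all rates by `alpha` divides every timescale (including the
#' relaxation time) by `alpha` and leaves the equilibrium distribution and the
#' validity ratio unchanged only if the exit rate is rescaled too; here all of
#' `forward`, `backward` and `exit_rate` are scaled.
#'
#' @param chain A [chain_spec()].
#' @param alpha Positive scale factor.
#' @return A rescaled `chain_spec`.
#' @export
scale_chain <- function(chain, alpha) {
  stopifnot(inherits(chain, "chain_spec"), alpha > 0)
  chain_spec(chain$forward * alpha, chain$backward * alpha,
             chain$exit_rate * alpha, chain$exit_index, chain$particles,
             n = chain$n)
}

#' Generate random chain fixtures
#'
#' Draws reproducible random chains with log-uniform rates, optionally
#' rescaling each chain's exit rate so the validity ratio
#' `rho = exit_rate * T_relax` hits a target value. Used for property tests;
#' exported because a reproducible fixture stream is useful interactively too.
#'
#' @param count Number of chains.
#' @param n_range Integer range (min, max) for the number of chain states
#'   (all generated chains have `n >= 2`).
#' @param rate_log_range Range of `log10(rate)` for the fast rates.
#' @param rho_target Optional target for `exit_rate * T_relax`; when set the
#'   exit rate is solved from the chain's relaxation time.
#' @param particles_range Integer range for the particle count.
#' @param seed Integer seed; the chain list is a pure function of the
#'   arguments.
#' @return A list of [chain_spec()] objects.
#' @examples
#' chains <- generate_random_chains(3, seed = 1)
#' length(chains)
#' @export
generate_random_chains <- function(count, n_range = c(2L, 12L),
                                   rate_log_range = c(-2, 2),
                                   rho_target = NULL,
                                   particles_range = c(1L, 1L),
                                   seed = 1L) {
  stopifnot(count >= 1, n_range[1] >= 2, n_range[2] >= n_range[1],
            rate_log_range[2] >= rate_log_range[1])
  withr_seed(seed, {
    purrr::map(seq_len(count), function(i) {
      n <- sample(seq.int(n_range[1], n_range[2]), 1L)
      lr <- stats::runif(2L * (n - 1L), rate_log_range[1], rate_log_range[2])
      f <- 10^lr[seq_len(n - 1L)]
      b <- 10^lr[n:(2L * (n - 1L))]
      m <- if (particles_range[2] > particles_range[1])
        sample(seq.int(particles_range[1], particles_range[2]), 1L)
      else particles_range[1]
      fn <- 10^stats::runif(1, rate_log_range[1], rate_log_range[2])
      ch <- chain_spec(f, b, fn, particles = m)
      if (!is.null(rho_target)) {
        tr <- relaxation_time(ch)
        ch <- chain_spec(f, b, rho_target / tr, particles = m)
      }
      ch
    })
  })
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
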
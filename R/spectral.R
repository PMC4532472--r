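#' Generator matrix of the chain with its slow exit (matrix A)
#'
#' Builds the chemical master equation generator for one particle on the
#' chain, including the slow exit: `dP/dt = A P` where `P_i(t)` is the
#' probability of occupying state `i`. `A` is tridiagonal with `forward` on
#' the subdiagonal, `backward` on the superdiagonal, and the exit rate
#' subtracted from diagonal entry `(u, u)` where `u` is the exit index.
#' Every column sums to zero except column `u`, which sums to `-exit_rate`
#' (the probability flux leaking to the absorbing state).
#'
#' @param chain A [chain_spec()].
#' @return An `n x n` numeric matrix.
#' @examples
#' build_generator_A(chain_spec(1, 1, exit_rate = 0.1))
#' @export
build_generator_A <- function(chain) {
  A <- build_generator_B(chain)
  u <- chain$exit_index
  A[u, u] <- A[u, u] - chain$exit_rate
  A
}

#' Generator matrix of the fast subsystem (matrix B)
#'
#' The generator of the chain with the exit reaction removed: a conservative
#' birth-death generator whose columns all sum to zero. `A - B` is a rank-one
#' perturbation with the single nonzero entry `-exit_rate` at `(u, u)`.
#'
#' @inheritParams build_generator_A
#' @return An `n x n` numeric matrix.
#' @export
build_generator_B <- function(chain) {
  stopifnot(inherits(chain, "chain_spec"))
  n <- chain$n
  B <- matrix(0, n, n)
  if (n > 1L) {
    idx <- seq_len(n - 1L)
    B[cbind(idx + 1L, idx)] <- chain$forward
    B[cbind(idx, idx + 1L)] <- chain$backward
  }
  diag(B) <- -colSums(B)
  dimnames(B) <- NULL
  B
}

# sorted real eigenvalues of a birth-death generator; complains if the
# spectrum is materially complex (it cannot be, for these matrices, beyond
# roundoff: they are similar to symmetric tridiagonals)
generator_eigen <- function(M, vectors = FALSE) {
  e <- eigen(M, symmetric = FALSE)
  rad <- max(Mod(e$values), .Machine$double.eps)
  if (any(abs(Im(e$values)) > 1e-9 * rad))
    stop("generator spectrum has non-negligible imaginary parts", call. = FALSE)
  ord <- order(Re(e$values))
  out <- list(values = Re(e$values)[ord])
  if (vectors) out$vectors <- Re(e$vectors)[, ord, drop = FALSE]
  out
}

#' Relaxation time of the fast subsystem
#'
#' The reciprocal of the spectral gap of the fast generator `B`:
#' `T_relax = 1 / |lambda_hat_(n-1)|`, where `lambda_hat_(n-1)` is the largest
#' nonzero eigenvalue of `B`. It is the timescale on which the fast chain
#' forgets a perturbation and settles to its equilibrium occupancy. For the
#' degenerate one-state chain it is 0 by convention.
#'
#' @inheritParams build_generator_A
#' @return A single non-negative number.
#' @examples
#' relaxation_time(chain_spec(2, 3, exit_rate = 0.01)) # 1 / (2 + 3)
#' @export
relaxation_time <- function(chain) {
  stopifnot(inherits(chain, "chain_spec"))
  if (chain$n == 1L) return(0)
  ev <- generator_eigen(build_generator_B(chain))$values
  rad <- max(abs(ev), .Machine$double.eps)
  nzero <- sum(abs(ev) <= 1e-9 * rad)
  if (nzero != 1L)
    stop("fast generator has ", nzero, " (near-)zero eigenvalues; the chain ",
         "is disconnected (some forward and backward rate both zero)",
         call. = FALSE)
  gap <- abs(ev[chain$n - 1L])
  1 / gap
}

#' Equilibrium distribution of the fast chain
#'
#' Solves for the stationary occupancy `pi` of the fast subsystem,
#' `B pi = 0`, `sum(pi) = 1`, by eliminating the last component: with
#' `beta = pi[1:(n-1)]`, the reduced linear system `Btilde beta + y = 0` is
#' solved where `Btilde` is the leading `(n-1)` block of `B` with
#' `backward[n-1]` subtracted across its last row and
#' `y = (0, ..., 0, backward[n-1])`. For a birth-death chain the result
#' satisfies detailed balance, `pi[i+1]/pi[i] = forward[i]/backward[i]`.
#'
#' @inheritParams build_generator_A
#' @return A probability vector of length `n`.
#' @examples
#' equilibrium_distribution(chain_spec(1, 1, exit_rate = 0)) # uniform
#' @export
equilibrium_distribution <- function(chain) {
  stopifnot(inherits(chain, "chain_spec"))
  n <- chain$n
  if (n == 1L) return(1)
  if (!is_irreducible(chain))
    stop("chain is reducible (a zero forward or backward rate); ",
         "no unique equilibrium", call. = FALSE)
  B <- build_generator_B(chain)
  Btilde <- B[seq_len(n - 1L), seq_len(n - 1L), drop = FALSE]
  bn1 <- chain$backward[n - 1L]
  Btilde[n - 1L, ] <- Btilde[n - 1L, ] - bn1
  y <- c(rep(0, n - 2L), bn1)
  beta <- tryCatch(solve(Btilde, -y),
                   error = function(e) stop("reduced equilibrium system is ",
                                            "singular: ", conditionMessage(e),
                                            call. = FALSE))
  pi <- c(beta, 1 - sum(beta))
  if (any(pi < -1e-10))
    stop("equilibrium solve produced negative probabilities", call. = FALSE)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Reduced reaction rate of the abridged system
#'
#' The abridgment collapses the chain plus exit into the single reaction
#' `S1 -> S(n+1)`. Two estimates of its rate are computed: `c_single`, the
#' magnitude of the dominant (smallest-magnitude) eigenvalue of the full
#' generator `A`; and `gamma = -exit_rate * pi[u]`, the exit flux evaluated at
#' the fast chain's equilibrium occupancy of the exit state. When the validity
#' ratio `rho = exit_rate * T_relax` is small the two agree to relative order
#' `rho`. For `m` independent particles the reduced rate is `m * |lambda_n|`.
#'
#' @inheritParams build_generator_A
#' @return A list with `gamma`, `c_single` (`|lambda_n|`), `c_m`
#'   (`particles * c_single`) and `rel_gap` (`|lambda_n - gamma| / |lambda_n|`).
#' @examples
#' r <- reduced_rate(chain_spec(1, 100, exit_rate = 1))
#' abs(r$gamma) # close to c1*c3/(c1+c2) = 1/101
#' @export
reduced_rate <- function(chain) {
  stopifnot(inherits(chain, "chain_spec"))
  if (chain$n == 1L) {
    g <- -chain$exit_rate
    return(list(gamma = g, c_single = abs(g),
                c_m = chain$particles * abs(g), rel_gap = 0))
  }
  pi <- equilibrium_distribution(chain)
  gamma <- -chain$exit_rate * pi[chain$exit_index]
  evA <- generator_eigen(build_generator_A(chain))$values
  lambda_n <- evA[chain$n]            # largest (closest to zero)
  c_single <- abs(lambda_n)
  rel_gap <- if (c_single > 0) abs(lambda_n - gamma) / c_single else 0
  list(gamma = gamma, c_single = c_single,
       c_m = chain$particles * c_single, rel_gap = rel_gap)
}

#' Timescale-separation validity check
#'
#' The abridgment is accurate when the fast chain relaxes much faster than the
#' slow reaction fires, i.e. when `rho = exit_rate * T_relax` is small
#' (equivalently `T_relax << 1/exit_rate`, the mean firing time of the slow
#' reaction). The default threshold 0.1 reflects that the relative error of
#' the reduced rate is of order `rho`, so `rho < 0.1` keeps it around 10%.
#'
#' @inheritParams build_generator_A
#' @param threshold Pass/fail cut on `rho` (default 0.1).
#' @return A list with `rho` and logical `valid`.
#' @examples
#' validity_check(chain_spec(1, 100, exit_rate = 1))
#' @export
validity_check <- function(chain, threshold = 0.1) {
  stopifnot(inherits(chain, "chain_spec"), threshold > 0)
  rho <- chain$exit_rate * relaxation_time(chain)
  list(rho = rho, valid = rho < threshold)
}

#' Full spectral report for a chain
#'
#' Computes and cross-checks every spectral quantity of the abridgment
#' analysis: the spectra of the full generator `A` and the fast generator
#' `B`, the relaxation time, the equilibrium occupancy, the reduced rate
#' (both the eigenvalue and its equilibrium-flux approximation `gamma`), and
#' the validity ratio. The eigenvalue interlacing bound
#' `0 <= lambda_hat_i - lambda_i <= exit_rate` (a rank-one perturbation
#' inequality) and `|lambda_n| <= exit_rate` are asserted entry-wise.
#'
#' @inheritParams validity_check
#' @return An object of class `spectral_report`; see [tidy.spectral_report()]
#'   and [glance.spectral_report()].
#' @examples
#' rep <- spectral_report(chain_spec(c(1, 1), c(1, 1), exit_rate = 0.01))
#' glance(rep)
#' @export
spectral_report <- function(chain, threshold = 0.1) {
  stopifnot(inherits(chain, "chain_spec"))
  n <- chain$n
  evA <- generator_eigen(build_generator_A(chain))$values
  evB <- if (n == 1L) 0 else generator_eigen(build_generator_B(chain))$values
  tol <- 1e-8 * max(abs(evA), abs(evB), 1)
  if (any(evA >= tol))
    stop("full generator has a non-negative eigenvalue", call. = FALSE)
  diffs <- evB - evA
  if (any(diffs < -tol) || any(diffs > chain$exit_rate + tol))
    stop("eigenvalue interlacing bound violated; generator assembly is ",
         "inconsistent", call. = FALSE)
  lambda_n <- evA[n]
  if (abs(lambda_n) > chain$exit_rate + tol)
    stop("|lambda_n| exceeds the exit rate; generator assembly is ",
         "inconsistent", call. = FALSE)
  t_relax <- relaxation_time(chain)
  pi <- if (is_irreducible(chain)) equilibrium_distribution(chain) else NULL
  rr <- reduced_rate_from(chain, pi, lambda_n)
  vc <- list(rho = chain$exit_rate * t_relax)
  vc$valid <- vc$rho < threshold
  structure(
    list(chain = chain, eigenvalues_A = evA, eigenvalues_B = evB,
         t_relax = t_relax, equilibrium = pi, gamma = rr$gamma,
         c_single = rr$c_single, c_m = rr$c_m, rel_gap = rr$rel_gap,
         rho = vc$rho, valid = vc$valid, threshold = threshold),
    class = "spectral_report"
  )
}

reduced_rate_from <- function(chain, pi, lambda_n) {
  if (is.null(pi))
    return(list(gamma = NA_real_, c_single = abs(lambda_n),
                c_m = chain$particles * abs(lambda_n), rel_gap = NA_real_))
  gamma <- -chain$exit_rate * pi[chain$exit_index]
  c_single <- abs(lambda_n)
  list(gamma = gamma, c_single = c_single,
       c_m = chain$particles * c_single,
       rel_gap = if (c_single > 0) abs(lambda_n - gamma) / c_single else 0)
}

#' @export
print.spectral_report <- function(x, ...) {
  cat("<spectral_report> chain with", x$chain$n, "states,",
      x$chain$particles, "particle(s)\n")
  cat("  T_relax   :", signif(x$t_relax, 6), "\n")
  cat("  |lambda_n|:", signif(x$c_single, 6),
      " gamma:", signif(x$gamma, 6),
      " rel gap:", signif(x$rel_gap, 3), "\n")
  cat("  reduced rate (m particles):", signif(x$c_m, 6), "\n")
  cat("  rho = exit_rate * T_relax :", signif(x$rho, 4),
      if (x$valid) "(valid" else "(NOT valid",
      "at threshold", paste0(x$threshold, ")"), "\n")
  invisible(x)
}

#' Tidy a spectral report into one row per eigenvalue
#'
#' @param x A [spectral_report()].
#' @param ... Unused.
#' @return A tibble with columns `index`, `eigenvalue_A`, `eigenvalue_B`,
#'   `shift` (their difference) and `equilibrium`.
#' @export
tidy.spectral_report <- function(x, ...) {
  tibble::tibble(
    index = seq_len(x$chain$n),
    eigenvalue_A = x$eigenvalues_A,
    eigenvalue_B = x$eigenvalues_B,
    shift = x$eigenvalues_B - x$eigenvalues_A,
    equilibrium = if (is.null(x$equilibrium)) NA_real_ else x$equilibrium
  )
}

#' One-row summary of a spectral report
#'
#' @param x A [spectral_report()].
#' @param ... Unused.
#' @return A one-row tibble with `n`, `particles`, `t_relax`, `lambda_n`,
#'   `gamma`, `c_single`, `c_m`, `rel_gap`, `rho`, `valid`.
#' @export
glance.spectral_report <- function(x, ...) {
  tibble::tibble(
    n = x$chain$n, particles = x$chain$particles, t_relax = x$t_relax,
    lambda_n = x$eigenvalues_A[x$chain$n], gamma = x$gamma,
    c_single = x$c_single, c_m = x$c_m, rel_gap = x$rel_gap,
    rho = x$rho, valid = x$valid
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
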
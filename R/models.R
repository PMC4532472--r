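#' Parameters of the multisite-phosphorylation bistable switch
#'
#' The switch couples a fast reversible phosphorylation chain on Cdh1
#' (`levels` phosphoforms, Cdh1P0 unphosphorylated through the top form) to
#' two slow reactions on Clb2: constant synthesis at `ks` and degradation
#' catalyzed by Cdh1 with per-particle efficiency decreasing with
#' phosphorylation level (weight `levels - i` for form `i`). Phosphorylation
#' of each Cdh1 particle is catalyzed by Clb2 at rate `k * Clb2`;
#' dephosphorylation runs at `k * kp`. `k` sets the chain's speed relative to
#' the slow reactions and is the knob that makes the reduction accurate
#' (large `k`) or not (small `k`).
#'
#' @param k Chain scale factor (> 0).
#' @param kp Dephosphorylation rate parameter (default 8).
#' @param ka Degradation rate constant (default 5.5e-4).
#' @param ks Synthesis rate (default `350 * ka`).
#' @param m Total Cdh1 particles (default 10).
#' @param levels Number of phosphoforms (default 10).
#' @return An object of class `switch_params`.
#' @examples
#' switch_params(k = 0.05)
#' @export
switch_params <- function(k, kp = 8, ka = 5.5e-4, ks = 350 * ka, m = 10L,
                          levels = 10L) {
  stopifnot(k > 0, kp > 0, ka > 0, ks > 0, m >= 1, levels >= 2)
  structure(list(k = k, kp = kp, ka = ka, ks = ks, m = as.integer(m),
                 levels = as.integer(levels)),
            class = "switch_params")
}

#' @export
print.switch_params <- function(x, ...) {
  cat("<switch_params> k =", x$k, " kp =", x$kp, " ka =", x$ka,
      " ks =", x$ks, " m =", x$m, " levels =", x$levels, "\n")
  invisible(x)
}

switch_weights <- function(p) rev(seq_len(p$levels))   # levels, ..., 1

#' Gillespie's three-species system and its abridgment
#'
#' The system `S1 <-> S2 -> S3` (rates `c1`, `c2`, `c3`) together with the
#' reduced reaction `S1 -> S3` whose rate is the equilibrium exit flux
#' `|gamma| = c1 c3 / (c1 + c2)` of the two-state chain.
#'
#' @param c1,c2,c3 Non-negative rate constants.
#' @return A list with the `original` and `reduced` networks, the `chain`
#'   specification, and the reduced `rate`.
#' @examples
#' sys <- build_three_species(1, 100, 1)
#' sys$rate
#' @export
build_three_species <- function(c1, c2, c3) {
  chain <- chain_spec(forward = c1, backward = c2, exit_rate = c3)
  original <- chain_to_network(chain)
  rate <- abs(reduced_rate(chain)$gamma)
  reduced <- reaction_network(
    c("S1", "S3"),
    list(reaction(c(-1L, 1L),
                  propensity_mass_action(rate, c(S1 = 1)), "abridged"))
  )
  list(original = original, reduced = reduced, chain = chain, rate = rate)
}

#' Build the full multisite-phosphorylation bistable switch
#'
#' Species are the Cdh1 phosphoforms `Cdh1P0 ... Cdh1P<levels-1>` and `Clb2`.
#' Reactions: phosphorylation `Cdh1P_i -> Cdh1P_(i+1)` with propensity
#' `k * Clb2 * X_i`; dephosphorylation with propensity `k * kp * X_(i+1)`;
#' synthesis of Clb2 at constant rate `ks`; degradation `Clb2 -> 0` with
#' propensity `ka * (sum_i (levels - i) X_i) * Clb2`. Total Cdh1 is conserved.
#'
#' @param p A [switch_params()].
#' @return A [reaction_network()].
#' @export
build_bistable_switch <- function(p) {
  stopifnot(inherits(p, "switch_params"))
  L <- p$levels
  forms <- paste0("Cdh1P", seq_len(L) - 1L)
  sp <- c(forms, "Clb2")
  N <- L + 1L
  shift <- function(i, j) { ch <- rep(0L, N); ch[i] <- -1L; ch[j] <- 1L; ch }
  reactions <- list()
  for (i in seq_len(L - 1L)) {
    reactions <- c(reactions, list(
      reaction(shift(i, i + 1L),
               propensity_mass_action(p$k, stats::setNames(c(1L, 1L),
                                                           c(forms[i], "Clb2"))),
               paste0("phos_", i - 1L)),
      reaction(shift(i + 1L, i),
               propensity_mass_action(p$k * p$kp,
                                      stats::setNames(1L, forms[i + 1L])),
               paste0("dephos_", i))
    ))
  }
  synth <- rep(0L, N); synth[N] <- 1L
  degr <- rep(0L, N); degr[N] <- -1L
  reactions <- c(reactions, list(
    reaction(synth, propensity_mass_action(p$ks), "clb2_synthesis"),
    reaction(degr,
             propensity_state_weighted(p$ka, c(Clb2 = 1L),
                                       stats::setNames(switch_weights(p),
                                                       forms)),
             "clb2_degradation")
  ))
  reaction_network(sp, reactions)
}

#' Default initial state of the full switch
#'
#' All Cdh1 particles unphosphorylated and the stated initial Clb2 copies.
#'
#' @param p A [switch_params()].
#' @param clb2 Initial Clb2 copy number (default 10).
#' @return A named integer state vector.
#' @export
switch_init_state <- function(p, clb2 = 10L) {
  stats::setNames(c(p$m, rep(0L, p$levels - 1L), clb2),
                  c(paste0("Cdh1P", seq_len(p$levels) - 1L), "Clb2"))
}

#' Build the reduced (abridged) bistable switch
#'
#' Two reactions on a single species: synthesis of Clb2 at `ks` and
#' degradation with the quasi-steady-state effective propensity
#' `ka * m * W(Clb2) * Clb2`, where `W(c) = sum_i (levels - i) pi_i(c)` and
#' `pi(c)` is the frozen phosphorylation chain's equilibrium (truncated
#' geometric with ratio `c / kp`). The effective rate is re-evaluated at the
#' current Clb2 before every firing, so the fast chain is summarized exactly
#' at its equilibrium given the instantaneous slow state.
#'
#' @param p A [switch_params()].
#' @return A [reaction_network()] with the single species `Clb2`.
#' @export
build_reduced_switch <- function(p) {
  stopifnot(inherits(p, "switch_params"))
  reaction_network("Clb2", list(
    reaction(1L, propensity_mass_action(p$ks), "clb2_synthesis"),
    reaction(-1L,
             propensity_chain_weighted(p$ka * p$m, target = "Clb2",
                                       driver = "Clb2", kp = p$kp,
                                       weights = switch_weights(p)),
             "clb2_degradation")
  ))
}

#' Quasi-steady-state degradation weight of the switch
#'
#' `W(c) = sum_i (levels - i) pi_i(c)` with `pi` the frozen-chain equilibrium
#' at Clb2 copy number `c`: the mean per-particle degradation efficiency once
#' the phosphorylation chain has relaxed. It is `5.5` at `c = kp` with 10
#' levels (uniform occupancy), tends to `levels` as `c -> 0` and to 1 as
#' `c -> Inf`.
#'
#' @param p A [switch_params()].
#' @param clb2 Clb2 copy number(s).
#' @return Numeric vector of weights.
#' @export
switch_qss_weight <- function(p, clb2) {
  vapply(clb2, chain_equilibrium_weight, numeric(1), kp = p$kp,
         weights = switch_weights(p))
}

#' Frozen phosphorylation chain of the switch at a given Clb2 level
#'
#' With Clb2 held fixed, each Cdh1 particle performs a reversible random walk
#' on the phosphoforms with uniform forward rate `k * Clb2` and backward rate
#' `k * kp`; the slow exit seen by this chain is the Clb2-changing reaction
#' with total propensity `exit_rate`.
#'
#' @param p A [switch_params()].
#' @param clb2 Clb2 copy number.
#' @param exit_rate Slow-reaction rate attributed to the chain (default 0:
#'   pure fast subsystem).
#' @return A [chain_spec()] with `m` particles.
#' @export
switch_frozen_chain <- function(p, clb2, exit_rate = 0) {
  L <- p$levels
  chain_spec(rep(p$k * clb2, L - 1L), rep(p$k * p$kp, L - 1L),
             exit_rate = exit_rate, particles = p$m)
}

#' Enzyme-mediated chain with slow enzyme turnover
#'
#' A chain `S1 <-> ... <-> Sn` whose every step (both directions) is
#' catalyzed by an enzyme E at rate `k0 * E`, with E synthesized at a
#' constant rate and degraded at rate `ku * X_u * E` (catalyzed by chain
#' state `u`). The chain species are untouched by the enzymic reactions and
#' E is untouched by the chain steps, so with E frozen the chain is exactly
#' a uniform-rate reversible chain.
#'
#' @param k0 Per-enzyme chain rate constant.
#' @param e_synthesis Constant E synthesis rate.
#' @param ku E degradation rate constant.
#' @param u Chain state catalyzing E degradation (1..n).
#' @param n Number of chain states.
#' @param m Total chain particles (for reference; set via the initial state).
#' @return A [reaction_network()] with species `S1..Sn` and `E`.
#' @export
build_enzyme_chain <- function(k0, e_synthesis, ku, u, n, m = 1L) {
  stopifnot(k0 > 0, e_synthesis > 0, ku > 0, u >= 1, u <= n, n >= 2)
  sp <- c(paste0("S", seq_len(n)), "E")
  N <- n + 1L
  shift <- function(i, j) { ch <- rep(0L, N); ch[i] <- -1L; ch[j] <- 1L; ch }
  reactions <- list()
  for (i in seq_len(n - 1L)) {
    reactions <- c(reactions, list(
      reaction(shift(i, i + 1L),
               propensity_mass_action(k0, stats::setNames(c(1L, 1L),
                                                          c(sp[i], "E"))),
               paste0("fwd_", i)),
      reaction(shift(i + 1L, i),
               propensity_mass_action(k0, stats::setNames(c(1L, 1L),
                                                          c(sp[i + 1L], "E"))),
               paste0("bwd_", i))
    ))
  }
  esyn <- rep(0L, N); esyn[N] <- 1L
  edeg <- rep(0L, N); edeg[N] <- -1L
  reactions <- c(reactions, list(
    reaction(esyn, propensity_mass_action(e_synthesis), "e_synthesis"),
    reaction(edeg,
             propensity_mass_action(ku, stats::setNames(c(1L, 1L),
                                                        c(sp[u], "E"))),
             "e_degradation")
  ))
  reaction_network(sp, reactions)
}

#' Relaxation time versus mean slow-reaction interval across Clb2 levels
#'
#' For each Clb2 copy number, computes the relaxation time of the frozen
#' phosphorylation chain and the mean interval between Clb2-changing (slow)
#' reaction events. The reduction is trustworthy where the relaxation curve
#' lies below the interval curve. The interval is `1 / (ks + a_deg(c))`; by
#' default the degradation propensity is taken at its maximum over Cdh1
#' configurations (`a_deg = ka * m * levels * c`, every particle
#' unphosphorylated), a conservative shortest-interval bound; set
#' `interval = "qss"` to use the frozen-chain equilibrium expectation
#' `a_deg = ka * m * W(c) * c` instead.
#'
#' @param p A [switch_params()].
#' @param clb2_values Integer Clb2 copy numbers (>= 0).
#' @param interval `"max"` (conservative bound, default) or `"qss"`.
#' @return A tibble with columns `clb2`, `t_relax`, `slow_interval`,
#'   `chain_reducible` (TRUE for `clb2 = 0`, where the frozen chain is the
#'   pure dephosphorylation chain).
#' @examples
#' relaxation_vs_firing_curve(switch_params(k = 5), c(1, 10, 20))
#' @export
relaxation_vs_firing_curve <- function(p, clb2_values,
                                       interval = c("max", "qss")) {
  stopifnot(inherits(p, "switch_params"), all(clb2_values >= 0))
  interval <- match.arg(interval)
  purrr::map_dfr(clb2_values, function(cc) {
    ch <- switch_frozen_chain(p, cc)
    a_deg <- if (interval == "max") p$ka * p$m * p$levels * cc
             else p$ka * p$m * switch_qss_weight(p, cc) * cc
    tibble::tibble(
      clb2 = cc,
      t_relax = relaxation_time(ch),
      slow_interval = 1 / (p$ks + a_deg),
      chain_reducible = !is_irreducible(ch)
    )
  })
}
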
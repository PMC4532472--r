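#' Define a discrete-state stochastic reaction network
#'
#' A network is a set of named species plus a list of reactions, each carrying
#' an integer state-change vector and a propensity rule. Propensity rules are
#' built with [propensity_mass_action()], [propensity_state_weighted()],
#' [propensity_chain_weighted()] or [propensity_function()].
#'
#' @param species Character vector of species names.
#' @param reactions List of [reaction()] objects.
#' @return An object of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   c("S1", "S2"),
#'   list(
#'     reaction(c(-1, 1), propensity_mass_action(2, c(S1 = 1)), "fwd"),
#'     reaction(c(1, -1), propensity_mass_action(1, c(S2 = 1)), "bwd")
#'   )
#' )
#' propensities(net, c(S1 = 3, S2 = 0))
#' @export
reaction_network <- function(species, reactions) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicate species names", call. = FALSE)
  if (!length(reactions)) stop("network needs at least one reaction",
                               call. = FALSE)
  reactions <- purrr::map(reactions, function(r) {
    if (!inherits(r, "abridger_reaction"))
      stop("reactions must be built with reaction()", call. = FALSE)
    if (length(r$change) != length(species))
      stop("change vector of reaction '", r$name, "' has length ",
           length(r$change), ", expected ", length(species), call. = FALSE)
    r
  })
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions)
    cat("  -", r$name, "[", r$prop$kind_name, "]\n")
  invisible(x)
}

#' A single reaction channel
#'
#' @param change Integer state-change vector, one entry per species.
#' @param propensity A propensity rule.
#' @param name Optional label used in error messages and printing.
#' @return An object of class `abridger_reaction`.
#' @export
reaction <- function(change, propensity, name = NULL) {
  change <- as.integer(change)
  if (!inherits(propensity, "abridger_propensity"))
    stop("propensity must be one of the propensity_*() rules", call. = FALSE)
  structure(list(change = change, prop = propensity,
                 name = name %||% "reaction"),
            class = "abridger_reaction")
}

new_propensity <- function(kind, kind_name, ...) {
  structure(c(list(kind = kind, kind_name = kind_name), list(...)),
            class = "abridger_propensity")
}

#' Mass-action propensity
#'
#' `rate * prod_i choose(x_i, order_i)`: the stochastic mass-action law with
#' the standard combinatorial count of distinct reactant combinations.
#'
#' @param rate Non-negative rate constant.
#' @param reactants Named integer vector of reactant orders, names being
#'   species; empty for a zeroth-order (synthesis) reaction.
#' @return A propensity rule.
#' @export
propensity_mass_action <- function(rate, reactants = integer()) {
  stopifnot(rate >= 0)
  new_propensity(1L, "mass-action", rate = as.numeric(rate),
                 reactants = reactants)
}

#' Mass-action propensity modulated by a linear state weight
#'
#' `rate * prod_i choose(x_i, order_i) * sum_j w_j x_j`. Used for reactions
#' whose effective rate constant is a weighted population count, e.g. a
#' degradation catalyzed by every phosphoform of an antagonist with
#' level-dependent efficiency.
#'
#' @inheritParams propensity_mass_action
#' @param weights Named numeric vector of state weights (names are species).
#' @return A propensity rule.
#' @export
propensity_state_weighted <- function(rate, reactants = integer(), weights) {
  stopifnot(rate >= 0, length(weights) >= 1)
  new_propensity(2L, "state-weighted", rate = as.numeric(rate),
                 reactants = reactants, weights = weights)
}

#' Propensity weighted by a frozen-chain equilibrium expectation
#'
#' `rate * x_target * sum_i w_i pi_i(x_driver)`, where `pi(x_driver)` is the
#' equilibrium occupancy of a reversible uniform-rate chain with forward rate
#' proportional to the driver copy number and backward rate proportional to
#' `kp`: a truncated geometric distribution with ratio `x_driver / kp`. This
#' is the quasi-steady-state effective rate law used by the reduced bistable
#' switch, where the fast phosphorylation chain is summarized by its
#' equilibrium.
#'
#' @param rate Non-negative rate constant (already including any particle
#'   multiplicity).
#' @param target Species whose copy number multiplies the propensity.
#' @param driver Species whose copy number sets the chain's geometric ratio.
#' @param kp Dephosphorylation rate parameter (geometric ratio denominator).
#' @param weights Numeric vector of per-level weights, level 0 first.
#' @return A propensity rule.
#' @export
propensity_chain_weighted <- function(rate, target, driver, kp, weights) {
  stopifnot(rate >= 0, kp > 0, length(weights) >= 1)
  new_propensity(3L, "chain-equilibrium", rate = as.numeric(rate),
                 target = target, driver = driver, kp = as.numeric(kp),
                 weights = as.numeric(weights))
}

#' Arbitrary propensity from an R function
#'
#' The function receives the named state vector and must return a single
#' non-negative finite number. Evaluated at every simulation step (no
#' caching), so this is the slow path; prefer the structured rules for long
#' runs.
#'
#' @param fn A function of the state vector.
#' @return A propensity rule.
#' @export
propensity_function <- function(fn) {
  stopifnot(is.function(fn))
  new_propensity(4L, "custom R", fun = fn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

species_index <- function(network, species) {
  i <- match(species, network$species)
  if (anyNA(i))
    stop("unknown species: ", paste(species[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}

# truncated-geometric chain expectation used by kind-3 propensities;
# shared by the reduced switch and the slow-interval curve
chain_equilibrium_weight <- function(driver_count, kp, weights) {
  L <- length(weights)
  r <- driver_count / kp
  pow <- r^(seq_len(L) - 1)
  sum(weights * pow) / sum(pow)
}

#' Evaluate all propensities of a network at a state
#'
#' Reference (pure R) evaluation of every reaction's propensity; the compiled
#' simulator implements the same rules, and the two are cross-checked in the
#' package tests.
#'
#' @param network A [reaction_network()].
#' @param state Non-negative integer state vector (named or positional).
#' @return A numeric vector, one propensity per reaction.
#' @export
propensities <- function(network, state) {
  state <- resolve_state(network, state)
  vapply(seq_along(network$reactions), function(j) {
    r <- network$reactions[[j]]
    a <- propensity_value(network, r$prop, state)
    if (!is.finite(a) || a < 0)
      stop("negative or non-finite propensity for reaction '", r$name, "'",
           call. = FALSE)
    a
  }, numeric(1))
}

propensity_value <- function(network, p, state) {
  ma <- function() {
    if (!length(p$reactants)) return(p$rate)
    i <- species_index(network, names(p$reactants))
    p$rate * prod(choose(state[i], p$reactants))
  }
  switch(p$kind,
    ma(),
    ma() * sum(p$weights * state[species_index(network, names(p$weights))]),
    {
      xt <- state[species_index(network, p$target)]
      if (xt <= 0) 0
      else p$rate * xt *
        chain_equilibrium_weight(state[species_index(network, p$driver)],
                                 p$kp, p$weights)
    },
    as.numeric(p$fun(stats::setNames(state, network$species)))
  )
}

resolve_state <- function(network, state) {
  N <- length(network$species)
  if (!is.null(names(state))) {
    x <- stats::setNames(rep(0, N), network$species)
    i <- species_index(network, names(state))
    x[i] <- state
    state <- x
  }
  if (length(state) != N)
    stop("state has length ", length(state), ", expected ", N, call. = FALSE)
  if (any(state < 0) || any(state != round(state)))
    stop("state must be non-negative integers", call. = FALSE)
  as.numeric(state)
}

# flatten a network into the descriptor lists the compiled engine consumes
network_descriptor <- function(network) {
  N <- length(network$species)
  nu <- vapply(network$reactions, function(r) r$change, integer(N))
  nu <- matrix(nu, nrow = N)
  props <- purrr::map(network$reactions, function(r) {
    p <- r$prop
    d <- list(kind = p$kind)
    if (p$kind %in% c(1L, 2L)) {
      d$rate <- p$rate
      d$ridx <- species_index(network, names(p$reactants))
      d$rord <- as.integer(p$reactants)
      if (p$kind == 2L) {
        w <- rep(0, N)
        w[species_index(network, names(p$weights))] <- p$weights
        d$w <- w
      }
    } else if (p$kind == 3L) {
      d$rate <- p$rate
      d$target <- species_index(network, p$target)
      d$driver <- species_index(network, p$driver)
      d$kp <- p$kp
      d$w <- p$weights
    } else {
      sp <- network$species
      fn <- p$fun
      d$fun <- function(x) as.numeric(fn(stats::setNames(x, sp)))
    }
    d
  })
  list(nu = nu, props = props)
}
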
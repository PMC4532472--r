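#' Simulate a reaction network with the Gillespie direct method
#'
#' Exact stochastic simulation: at each step the waiting time is drawn as
#' `tau = log(1/r1) / a0` and the firing channel is the smallest index `j`
#' with `sum(a[1:j]) > r2 * a0`, with the two uniforms drawn in that fixed
#' order so trajectories are bit-reproducible given a seed. The event loop is
#' compiled; time-fraction occupancies are accumulated online (after
#' `burn_in`), so thinned or unrecorded trajectories still yield unbiased
#' stationary-distribution estimates.
#'
#' @param network A [reaction_network()].
#' @param init_state Non-negative integer initial state (named or positional).
#' @param t_end Simulation horizon (> 0).
#' @param seed Integer seed; every random draw derives from it.
#' @param stop_predicate Optional early-stopping rule: either a function of
#'   the named state vector returning `TRUE` to stop, or a list
#'   `list(species =, value =, op =)` stopping the first time that species
#'   satisfies `op` (`">="`, the default, or `"<="`) against `value` (the
#'   fast path).
#' @param record `"jumps"` (every event; errors beyond `max_records` events),
#'   `"thin"` (states sampled on a `thin_dt` grid), or `"none"`.
#' @param thin_dt Grid spacing for `record = "thin"` (default `t_end / 1000`).
#' @param burn_in Time discarded before occupancy accumulation (default 0).
#' @param max_records Guard on the number of recorded jumps (default 2e6).
#' @return A tibble of class `ssa_trajectory` with a `time` column and one
#'   column per species; attributes carry `final_time`, `final_state`,
#'   `stopped`, `stop_time`, `n_steps`, `seed`, `burn_in` and the online
#'   `occupancy` tables.
#' @examples
#' net <- reaction_network("S", list(
#'   reaction(1L, propensity_mass_action(1), "birth"),
#'   reaction(-1L, propensity_mass_action(0.2, c(S = 1)), "death")
#' ))
#' traj <- simulate_ssa(net, c(S = 0), t_end = 50, seed = 1)
#' tail(traj)
#' @export
simulate_ssa <- function(network, init_state, t_end, seed,
                         stop_predicate = NULL,
                         record = c("jumps", "thin", "none"),
                         thin_dt = NULL, burn_in = 0, max_records = 2e6) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0, burn_in >= 0,
            burn_in < t_end)
  record <- match.arg(record)
  x0 <- resolve_state(network, init_state)
  desc <- network_descriptor(network)

  stop_species <- 0L; stop_value <- Inf; stop_dir <- 1L; stop_fun <- NULL
  if (!is.null(stop_predicate)) {
    if (is.list(stop_predicate)) {
      stop_species <- species_index(network, stop_predicate$species)
      stop_value <- stop_predicate$value
      op <- stop_predicate$op %||% ">="
      if (!op %in% c(">=", "<="))
        stop("stop_predicate$op must be \">=\" or \"<=\"", call. = FALSE)
      stop_dir <- if (op == ">=") 1L else -1L
    } else if (is.function(stop_predicate)) {
      sp <- network$species
      f <- stop_predicate
      stop_fun <- function(x) isTRUE(f(stats::setNames(x, sp)))
    } else stop("stop_predicate must be a function or list(species=, value=)",
                call. = FALSE)
  }
  record_mode <- c(jumps = 1L, thin = 2L, none = 0L)[[record]]
  if (is.null(thin_dt)) thin_dt <- t_end / 1000
  res <- withr_seed(as.integer(seed), {
    ssa_run_cpp(desc$props, desc$nu, x0, t_end, burn_in, record_mode,
                thin_dt, max_records, stop_species, stop_value, stop_dir,
                stop_fun, TRUE)
  })
  states <- res$states
  colnames(states) <- network$species
  traj <- tibble::as_tibble(as.data.frame(states))
  traj <- dplyr::mutate(traj, time = res$times, .before = 1)
  occ <- stats::setNames(res$occupancy, network$species)
  attr(traj, "species") <- network$species
  attr(traj, "final_time") <- res$final_time
  attr(traj, "final_state") <- stats::setNames(as.numeric(res$final_state),
                                               network$species)
  attr(traj, "stopped") <- res$stopped
  attr(traj, "stop_time") <- res$stop_time
  attr(traj, "n_steps") <- res$nsteps
  attr(traj, "seed") <- as.integer(seed)
  attr(traj, "burn_in") <- burn_in
  attr(traj, "record") <- record
  attr(traj, "occupancy") <- occ
  class(traj) <- c("ssa_trajectory", class(traj))
  traj
}

#' Time-fraction distribution of a species along a trajectory
#'
#' Estimates the stationary distribution of one species as the fraction of
#' simulated time (after `burn_in`) spent at each copy number. For fully
#' recorded trajectories the piecewise-constant path is integrated exactly
#' from the jump records; for thinned or unrecorded trajectories the
#' occupancy table accumulated online during simulation is used (exact too,
#' but only at the `burn_in` the simulation was run with).
#'
#' @param traj An [simulate_ssa()] trajectory.
#' @param species Species name (or index).
#' @param burn_in Time discarded from the start (default: the trajectory's
#'   own burn-in).
#' @return A tibble of class `distribution_estimate` with columns `copies`
#'   and `prob` (summing to 1).
#' @examples
#' net <- reaction_network("S", list(
#'   reaction(1L, propensity_mass_action(1), "birth"),
#'   reaction(-1L, propensity_mass_action(0.5, c(S = 1)), "death")
#' ))
#' traj <- simulate_ssa(net, c(S = 0), t_end = 200, seed = 7)
#' time_fraction_distribution(traj, "S")
#' @export
time_fraction_distribution <- function(traj, species, burn_in = NULL) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  sp_names <- attr(traj, "species")
  if (is.numeric(species)) species <- sp_names[species]
  if (!species %in% sp_names) stop("unknown species '", species, "'",
                                   call. = FALSE)
  final_time <- attr(traj, "final_time")
  if (is.null(burn_in)) burn_in <- attr(traj, "burn_in")
  if (burn_in >= final_time)
    stop("burn_in (", burn_in, ") leaves no post-burn-in time window",
         call. = FALSE)
  if (attr(traj, "record") == "jumps") {
    tt <- traj$time
    xx <- traj[[species]]
    edges <- c(pmax(tt, burn_in), final_time)
    dur <- pmax(diff(edges), 0)
    agg <- tapply(dur, xx, sum)
    probs <- as.numeric(agg) / (final_time - burn_in)
    out <- tibble::tibble(copies = as.integer(names(agg)), prob = probs)
    out <- dplyr::arrange(dplyr::filter(out, .data$prob > 0), .data$copies)
  } else {
    if (!isTRUE(all.equal(burn_in, attr(traj, "burn_in"))))
      stop("thinned/unrecorded trajectories only support the burn_in the ",
           "simulation was run with (", attr(traj, "burn_in"), ")",
           call. = FALSE)
    occ <- attr(traj, "occupancy")[[species]]
    if (!length(occ) || sum(occ) <= 0)
      stop("empty occupancy table for '", species, "'", call. = FALSE)
    out <- tibble::tibble(copies = seq_along(occ) - 1L,
                          prob = occ / sum(occ))
    out <- dplyr::filter(out, .data$prob > 0)
  }
  new_distribution_estimate(out)
}

new_distribution_estimate <- function(tbl) {
  stopifnot(all(c("copies", "prob") %in% names(tbl)))
  if (abs(sum(tbl$prob) - 1) > 1e-9)
    stop("distribution masses must sum to 1", call. = FALSE)
  class(tbl) <- c("distribution_estimate", class(tbl))
  tbl
}

#' Build a distribution estimate from copy numbers and masses
#'
#' @param copies Integer copy numbers (distinct, non-negative).
#' @param prob Probability masses summing to 1.
#' @return A `distribution_estimate` tibble.
#' @export
distribution_estimate <- function(copies, prob) {
  stopifnot(length(copies) == length(prob), !anyDuplicated(copies),
            all(prob >= 0))
  new_distribution_estimate(
    dplyr::arrange(tibble::tibble(copies = as.integer(copies),
                                  prob = as.numeric(prob)), .data$copies))
}

#' Mean of a distribution estimate
#' @param x A `distribution_estimate`.
#' @param ... Unused.
#' @export
mean.distribution_estimate <- function(x, ...) sum(x$copies * x$prob)

#' Write / read a trajectory as TSV with a JSON metadata sidecar
#'
#' The TSV has a `time` column plus one column per species; metadata (seed,
#' horizon, burn-in, stopping information) goes to `<path>.meta.json`.
#'
#' @param traj An `ssa_trajectory`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(species = attr(traj, "species"),
               final_time = attr(traj, "final_time"),
               stopped = attr(traj, "stopped"),
               stop_time = attr(traj, "stop_time"),
               n_steps = attr(traj, "n_steps"),
               seed = attr(traj, "seed"),
               burn_in = attr(traj, "burn_in"),
               record = attr(traj, "record"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tbl <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  num <- c("final_time", "stop_time", "n_steps", "burn_in")
  meta[num] <- lapply(meta[num], function(v)
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v)))
  for (f in setdiff(names(meta), "species")) attr(tbl, f) <- meta[[f]]
  attr(tbl, "species") <- meta$species
  class(tbl) <- c("ssa_trajectory", class(tbl))
  tbl
}

#' Write a distribution estimate as two-column TSV
#'
#' @param dist A `distribution_estimate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  utils::write.table(data.frame(copy_number = dist$copies,
                                probability = dist$prob),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
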
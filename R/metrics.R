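#' Percent L1 distance between two copy-number distributions
#'
#' `100 * sum_x |p(x) - q(x)|` over the union of supports: the "distribution
#' density error", ranging from 0 (identical) to 200 (disjoint supports).
#' Both inputs must be normalized mass functions over integer copy numbers.
#'
#' @param p,q `distribution_estimate` tibbles (columns `copies`, `prob`).
#' @return A percentage in `[0, 200]`.
#' @examples
#' a <- distribution_estimate(0:1, c(0.5, 0.5))
#' b <- distribution_estimate(0, 1)
#' density_error(a, b) # 100
#' @export
density_error <- function(p, q) {
  check_dist <- function(d, lab) {
    if (!all(c("copies", "prob") %in% names(d)))
      stop(lab, " must have columns 'copies' and 'prob'", call. = FALSE)
    if (abs(sum(d$prob) - 1) > 1e-8)
      stop(lab, " is not normalized (mass ", sum(d$prob), ")", call. = FALSE)
  }
  check_dist(p, "p"); check_dist(q, "q")
  joined <- dplyr::full_join(
    dplyr::select(tibble::as_tibble(p), "copies", p_mass = "prob"),
    dplyr::select(tibble::as_tibble(q), "copies", q_mass = "prob"),
    by = "copies"
  )
  joined <- tidyr::replace_na(joined, list(p_mass = 0, q_mass = 0))
  100 * sum(abs(joined$p_mass - joined$q_mass))
}

#' Compare the full and reduced bistable switch by simulation
#'
#' Runs both the full multisite switch and its abridged form from the same
#' initial Clb2 copy number, estimates the time-fraction distribution of Clb2
#' in each (after burn-in), and reports the percent L1 distance between the
#' two distributions. This is the package's headline validation of the
#' reduction: the error is small when the chain scale `k` makes the
#' phosphorylation chain fast, and grows as `k` shrinks until the reduced
#' model's bimodality is no longer shared by the full model.
#'
#' @param p A [switch_params()].
#' @param t_end Simulation horizon in time units (default 1e6, the scale at
#'   which both attractors are well sampled for slow switching).
#' @param seed Integer seed; the full and reduced runs use seeds derived
#'   from it so they are independent but reproducible.
#' @param clb2_init Initial Clb2 copies (default 10).
#' @param burn_in Discarded initial time span (default 1% of `t_end`).
#' @return A list with `error_pct`, `dist_full`, `dist_reduced`, and the
#'   elapsed step counts `steps_full`, `steps_reduced`.
#' @examples
#' \donttest{
#' res <- compare_switch_models(switch_params(k = 0.5), t_end = 2e4, seed = 1)
#' res$error_pct
#' }
#' @export
compare_switch_models <- function(p, t_end = 1e6, seed = 1L,
                                  clb2_init = 10L, burn_in = 0.01 * t_end) {
  stopifnot(inherits(p, "switch_params"), t_end > 0)
  full <- build_bistable_switch(p)
  red <- build_reduced_switch(p)
  seed <- as.integer(seed)
  traj_full <- simulate_ssa(full, switch_init_state(p, clb2_init),
                            t_end = t_end, seed = seed, record = "none",
                            burn_in = burn_in)
  traj_red <- simulate_ssa(red, c(Clb2 = clb2_init), t_end = t_end,
                           seed = seed + 1L, record = "none",
                           burn_in = burn_in)
  d_full <- time_fraction_distribution(traj_full, "Clb2")
  d_red <- time_fraction_distribution(traj_red, "Clb2")
  list(error_pct = density_error(d_full, d_red),
       dist_full = d_full, dist_reduced = d_red,
       steps_full = attr(traj_full, "n_steps"),
       steps_reduced = attr(traj_red, "n_steps"))
}

#' Density error of the switch reduction across chain scales
#'
#' Convenience sweep of [compare_switch_models()] over several chain scales,
#' averaging over seeds.
#'
#' @param k_values Chain scale factors.
#' @param t_end Horizon per run (single value or one per `k`).
#' @param seeds Integer seeds averaged over.
#' @param ... Passed to [switch_params()].
#' @return A tibble with columns `k`, `t_end`, `error_pct` (mean over seeds),
#'   `error_sd` and `n_seeds`.
#' @export
switch_error_sweep <- function(k_values, t_end = 1e6, seeds = 1L, ...) {
  t_end <- rep_len(t_end, length(k_values))
  purrr::map2_dfr(k_values, t_end, function(k, te) {
    errs <- purrr::map_dbl(seeds, function(s)
      compare_switch_models(switch_params(k = k, ...), t_end = te,
                            seed = s)$error_pct)
    tibble::tibble(k = k, t_end = te, error_pct = mean(errs),
                   error_sd = stats::sd(errs), n_seeds = length(seeds))
  })
}

#' Count the modes of a copy-number distribution
#'
#' Local maxima of the mass function after light smoothing over the integer
#' support (mass below `min_mass` is ignored), used to classify distributions
#' as unimodal or bimodal.
#'
#' @param dist A `distribution_estimate`.
#' @param smooth Moving-average half-width in copies (default 2).
#' @param min_prominence Minimum peak height relative to the maximum
#'   (default 0.05).
#' @return A tibble with one row per detected mode: `copies`, `prob`.
#' @export
distribution_modes <- function(dist, smooth = 2L, min_prominence = 0.05) {
  support <- seq(min(dist$copies), max(dist$copies))
  mass <- rep(0, length(support))
  mass[match(dist$copies, support)] <- dist$prob
  ker <- rep(1, 2L * smooth + 1L)
  sm <- stats::filter(c(rep(0, smooth), mass, rep(0, smooth)), ker / sum(ker),
                      sides = 2)
  sm <- as.numeric(sm)[(smooth + 1L):(smooth + length(support))]
  is_peak <- vapply(seq_along(sm), function(i) {
    left <- if (i == 1L) 0 else sm[i - 1L]
    right <- if (i == length(sm)) 0 else sm[i + 1L]
    sm[i] >= left && sm[i] > right
  }, logical(1))
  peaks <- which(is_peak & sm >= min_prominence * max(sm))
  # merge flat-topped plateaus into a single mode
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > 2L * smooth)
    peaks <- peaks[keep]
  }
  tibble::tibble(copies = support[peaks], prob = mass[peaks])
}
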
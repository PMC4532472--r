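#' Run a declared experiment from a YAML configuration file
#'
#' Executes one of the package's analyses as described by a small YAML
#' document and writes its outputs (TSV tables, JSON reports) under the
#' configured output directory. All randomness derives from the configured
#' seed, so a config run is reproducible bit-for-bit.
#'
#' The schema (fields in brackets optional):
#' \preformatted{
#' task: analyze_chain | simulate | exit_time | compare_switch | gen_fixtures
#' out: <output directory>
#' [seed: <integer, default 1>]
#' # analyze_chain / exit_time:
#' chain: {forward: [..], backward: [..], exit_rate: x,
#'         [exit_index: u], [particles: m]}
#' [threshold: 0.1]                       # analyze_chain
#' [t_max_multiples: 8]                   # exit_time
#' # simulate:
#' model: {type: chain | three_species | three_species_reduced |
#'               switch | switch_reduced | enzyme_chain, ...type fields}
#' t_end: <horizon>;  [burn_in];  [record: jumps|thin|none];  [thin_dt]
#' init: {<species>: <copies>, ...}
#' [distribution_of: <species>]
#' # compare_switch:
#' k: <chain scale>;  [t_end: 1e6];  [clb2_init: 10];  [burn_in]
#' [kp, ka, ks, m, levels]
#' # gen_fixtures:
#' count: <n>;  [n_range];  [rate_log_range];  [rho_target]
#' }
#'
#' @param path Path to the YAML config.
#' @return A list with the task's results (also written to disk), invisibly.
#' @export
run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(field, where = cfg, label = field) {
    if (is.null(where[[field]]))
      stop("config field '", label, "' is required", call. = FALSE)
    where[[field]]
  }
  task <- need("task")
  out_dir <- need("out")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  res <- switch(task,
    analyze_chain = {
      chain <- config_chain(need("chain"))
      rep <- spectral_report(chain, threshold = cfg$threshold %||% 0.1)
      out <- c(as.list(glance(rep)),
               list(eigenvalues_A = rep$eigenvalues_A,
                    eigenvalues_B = rep$eigenvalues_B,
                    equilibrium = rep$equilibrium))
      jsonlite::write_json(out, file.path(out_dir, "spectral_report.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    },
    exit_time = {
      chain <- config_chain(need("chain"))
      mult <- cfg$t_max_multiples %||% 8
      dev <- exponential_deviation(chain, t_max_multiples = mult)
      lam <- reduced_rate(chain)$c_single
      tg <- seq(0, mult / lam, length.out = 501)
      curve <- survival_function(chain, tg)
      utils::write.table(as.data.frame(curve),
                         file.path(out_dir, "survival.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      jsonlite::write_json(list(exponential_deviation = dev,
                                rate = lam),
                           file.path(out_dir, "exit_time.json"),
                           auto_unbox = TRUE, digits = NA)
      list(deviation = dev, curve = curve)
    },
    simulate = {
      net <- config_model(need("model"))
      init <- unlist(need("init"))
      t_end <- need("t_end")
      traj <- simulate_ssa(net, init, t_end = t_end, seed = seed,
                           record = cfg$record %||% "jumps",
                           thin_dt = cfg$thin_dt,
                           burn_in = cfg$burn_in %||% 0)
      write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
      if (!is.null(cfg$distribution_of)) {
        d <- time_fraction_distribution(traj, cfg$distribution_of)
        write_distribution(d, file.path(out_dir, "distribution.tsv"))
      }
      traj
    },
    compare_switch = {
      p <- switch_params(k = need("k"), kp = cfg$kp %||% 8,
                         ka = cfg$ka %||% 5.5e-4,
                         ks = cfg$ks %||% (350 * (cfg$ka %||% 5.5e-4)),
                         m = cfg$m %||% 10L, levels = cfg$levels %||% 10L)
      t_end <- cfg$t_end %||% 1e6
      res <- compare_switch_models(p, t_end = t_end, seed = seed,
                                   clb2_init = cfg$clb2_init %||% 10L,
                                   burn_in = cfg$burn_in %||% (0.01 * t_end))
      write_distribution(res$dist_full, file.path(out_dir, "dist_full.tsv"))
      write_distribution(res$dist_reduced,
                         file.path(out_dir, "dist_reduced.tsv"))
      jsonlite::write_json(list(k = p$k, t_end = t_end, seed = seed,
                                error_pct = res$error_pct),
                           file.path(out_dir, "density_error.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    },
    gen_fixtures = {
      chains <- generate_random_chains(
        count = need("count"),
        n_range = cfg$n_range %||% c(2L, 12L),
        rate_log_range = cfg$rate_log_range %||% c(-2, 2),
        rho_target = cfg$rho_target,
        seed = seed)
      jsonlite::write_json(purrr::map(chains, unclass),
                           file.path(out_dir, "chains.json"),
                           auto_unbox = TRUE, digits = NA)
      chains
    },
    stop("unknown task '", task, "'; expected analyze_chain, exit_time, ",
         "simulate, compare_switch or gen_fixtures", call. = FALSE)
  )
  invisible(res)
}

config_chain <- function(spec) {
  bad <- setdiff(names(spec),
                 c("forward", "backward", "exit_rate", "exit_index",
                   "particles", "n"))
  if (length(bad))
    stop("unknown chain field(s): ", paste0("chain.", bad, collapse = ", "),
         call. = FALSE)
  tryCatch(
    chain_spec(forward = unlist(spec$forward) %||% numeric(),
               backward = unlist(spec$backward) %||% numeric(),
               exit_rate = spec$exit_rate %||% 0,
               exit_index = spec$exit_index,
               particles = spec$particles %||% 1L,
               n = spec$n),
    error = function(e) stop("invalid 'chain': ", conditionMessage(e),
                             call. = FALSE))
}

config_model <- function(model) {
  type <- model$type %||% stop("config field 'model.type' is required",
                               call. = FALSE)
  switch(type,
    chain = chain_to_network(config_chain(model[setdiff(names(model),
                                                        "type")])),
    three_species = build_three_species(model$c1, model$c2,
                                        model$c3)$original,
    three_species_reduced = build_three_species(model$c1, model$c2,
                                                model$c3)$reduced,
    switch = build_bistable_switch(config_switch_params(model)),
    switch_reduced = build_reduced_switch(config_switch_params(model)),
    enzyme_chain = build_enzyme_chain(model$k0, model$e_synthesis, model$ku,
                                      model$u, model$n, model$m %||% 1L),
    stop("unknown model.type '", type, "'", call. = FALSE)
  )
}

config_switch_params <- function(model) {
  if (is.null(model$k))
    stop("config field 'model.k' is required for switch models",
         call. = FALSE)
  switch_params(k = model$k, kp = model$kp %||% 8, ka = model$ka %||% 5.5e-4,
                ks = model$ks %||% (350 * (model$ka %||% 5.5e-4)),
                m = model$m %||% 10L, levels = model$levels %||% 10L)
}
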
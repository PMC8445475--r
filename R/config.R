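#' Run a seeded ensemble of chain simulations
#'
#' Generates and integrates `n_runs` independent chains; realization `k`
#' is seeded deterministically with `base_seed + k - 1`, so an ensemble is
#' reproducible from its base seed alone. Failures of individual
#' realizations are caught, recorded and skipped.
#'
#' @param n_runs number of realizations.
#' @param base_seed base RNG seed.
#' @param n_lumens lumens per chain.
#' @param t_end integration horizon.
#' @param params a [dimensionless_params()].
#' @param profile optional [pumping_profile()].
#' @param chain_args extra arguments for [generate_chain()].
#' @param integrate_args extra arguments for [integrate_chain()]
#'   (e.g. `model`, `snapshot_times`, tolerances).
#' @return List of class `lumen_ensemble`: `trajectories` (one per
#'   successful realization, each with a `seed` element), `failures`
#'   (named list of error messages), `base_seed`, `n_runs`.
#' @export
run_ensemble <- function(n_runs, base_seed, n_lumens = 100, t_end = 1e3,
                         params = dimensionless_params(), profile = NULL,
                         chain_args = list(), integrate_args = list()) {
  stopifnot(n_runs >= 1)
  trajs <- list(); failures <- list()
  for (k in seq_len(n_runs)) {
    seed_k <- base_seed + k - 1
    res <- tryCatch({
      ch <- do.call(generate_chain, c(list(n_lumens = n_lumens,
                                           seed = seed_k, params = params,
                                           profile = profile), chain_args))
      tr <- do.call(integrate_chain, c(list(chain = ch, t_end = t_end),
                                       integrate_args))
      tr$seed <- seed_k
      tr
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures[[as.character(seed_k)]] <- conditionMessage(res)
    else trajs[[length(trajs) + 1L]] <- res
  }
  structure(list(trajectories = trajs, failures = failures,
                 base_seed = base_seed, n_runs = n_runs),
            class = "lumen_ensemble")
}

#' @export
print.lumen_ensemble <- function(x, ...) {
  cat(sprintf("Lumen ensemble: %d/%d realizations (base seed %d)\n",
              length(x$trajectories), x$n_runs, x$base_seed))
  if (length(x$failures))
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

.config_schema <- list(
  params = c("epsilon", "chi_v", "chi_s", "tau_v", "tau_s", "theta",
             "ell0bar"),
  physical = c("gamma", "gamma_c", "e0", "eta", "lambda_v", "lambda_s",
               "D", "c0", "p0", "RT", "L_scale", "ell0", "L_sys"),
  scenario = c("kind", "n_lumens", "A_mean", "A_sd", "ell_mean", "ell_sd",
               "size_ratio", "ja1", "ja2", "seed"),
  pumping = c("kind", "j0", "delta_j", "mu_g", "sigma"),
  integrator = c("t_end", "rtol", "atol", "L_min", "ell_min", "model",
                 "record_steps"),
  ensemble = c("n_runs", "base_seed"))

#' Validate a raw run configuration
#'
#' Checks section and key names against the schema, enforces the physical
#' constraints through the corresponding constructors, and requires a
#' seed. Error messages are aggregated.
#'
#' @param raw named list (e.g. from [read_config()]): sections `params`
#'   (or `physical`), `scenario`, optional `pumping`, `integrator`,
#'   optional `ensemble`.
#' @return The validated configuration (class `run_config`) with
#'   constructed parameter objects attached.
#' @export
validate_config <- function(raw) {
  errors <- character(0)
  unknown_sections <- setdiff(names(raw), names(.config_schema))
  if (length(unknown_sections))
    errors <- c(errors, paste("unknown section(s):",
                              paste(unknown_sections, collapse = ", ")))
  for (sec in intersect(names(raw), names(.config_schema))) {
    bad <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(bad))
      errors <- c(errors, paste0("unknown key(s) in '", sec, "': ",
                                 paste(bad, collapse = ", ")))
  }
  params <- tryCatch({
    if (!is.null(raw$physical)) {
      dimensionless_groups(do.call(physical_params, raw$physical))$params
    } else do.call(dimensionless_params, raw$params %||% list())
  }, error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  profile <- NULL
  if (!is.null(raw$pumping)) {
    profile <- tryCatch(do.call(pumping_profile, raw$pumping),
                        error = function(e) {
                          errors <<- c(errors, conditionMessage(e)); NULL })
    if (!is.null(profile) && profile$kind == "gaussian" &&
        profile$sigma >= 0.075)
      errors <- c(errors, paste(
        "gaussian pumping sigma must be < 0.075 (the basal-pumping",
        "threshold construction is undefined beyond it)"))
  }
  sc <- raw$scenario
  if (is.null(sc$kind) || !sc$kind %in% c("chain", "two_lumen"))
    errors <- c(errors, "scenario$kind must be 'chain' or 'two_lumen'")
  if (is.null(sc$seed) && is.null(raw$ensemble$base_seed))
    errors <- c(errors,
                "a seed is required (scenario$seed or ensemble$base_seed)")
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  structure(list(raw = raw, params = params, profile = profile),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' @param path path to a YAML file with the sections documented in
#'   [validate_config()].
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Execute a validated configuration
#'
#' @param config a `run_config` from [validate_config()]/[read_config()].
#' @return For `scenario$kind == "chain"`: a `lumen_ensemble` (single
#'   realization if no `ensemble` section). For `"two_lumen"`: a
#'   `lumen_trajectory` with an added `fate` element.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  raw <- config$raw
  sc <- raw$scenario
  it <- raw$integrator %||% list()
  t_end <- it$t_end %||% 1e3
  iargs <- it[intersect(names(it), c("rtol", "atol", "L_min", "ell_min",
                                     "model", "record_steps"))]
  if (sc$kind == "two_lumen") {
    ch <- two_lumen_state(
      size_ratio = sc$size_ratio %||% 1.1, ja1 = sc$ja1 %||% 0,
      ja2 = sc$ja2 %||% 0, chi_v = config$params$chi_v,
      chi_s = config$params$chi_s,
      tau_s = config$params$tau_s / config$params$tau_v,
      epsilon = config$params$epsilon, theta = config$params$theta,
      ell0bar = config$params$ell0bar)
    tr <- do.call(integrate_chain,
                  c(list(chain = ch, t_end = t_end, record_steps = TRUE),
                    iargs[setdiff(names(iargs), "record_steps")]))
    tr$fate <- classify_fate(tr)
    return(tr)
  }
  ens <- raw$ensemble %||% list(n_runs = 1)
  run_ensemble(
    n_runs = ens$n_runs %||% 1,
    base_seed = ens$base_seed %||% sc$seed,
    n_lumens = sc$n_lumens %||% 100, t_end = t_end,
    params = config$params, profile = config$profile,
    chain_args = sc[intersect(names(sc),
                              c("A_mean", "A_sd", "ell_mean", "ell_sd"))],
    integrate_args = iargs)
}

#' Write a trajectory to plain-text files
#'
#' Writes `<prefix>_events.csv` (the event log), optionally
#' `<prefix>_snapshots.csv` (long format: time, id, x, L, N, C) and
#' `<prefix>_summary.json` (final count, final lumen positions, survivor
#' flag, status, seed).
#'
#' @param traj a `lumen_trajectory`.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_trajectory <- function(traj, prefix) {
  files <- character(0)
  f <- paste0(prefix, "_events.csv")
  utils::write.csv(traj$events, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(traj$snapshots)) {
    f <- paste0(prefix, "_snapshots.csv")
    utils::write.csv(traj$snapshots, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(
    n0 = traj$n0, n_final = nrow(traj$final$lumens),
    t_final = traj$final$time, survivor = traj$survivor,
    status = traj$status, seed = traj$seed %||% NA,
    final_positions = traj$final$lumens$x / traj$final$L_sys),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
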
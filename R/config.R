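#' Default experiment configuration
#'
#' Returns the full configuration for one of the three bundled experiments,
#' with every default matching the study conditions: growth rates
#' `sigma = (1, 2, 3)`, a 100-node 1D grid on `[0, 2*pi)` (or a 20 x 20
#' pixel grid in 2D), 60 trials with observational noise 0.005 recorded at
#' nodes 3, 21, 47, 88 for the ensemble.
#'
#' @param experiment `"1d-sine"`, `"2d-digits"`, or `"ensemble"`.
#' @return An object of class `nf_config` (nested named list).
#' @export
default_config <- function(experiment = c("1d-sine", "2d-digits",
                                          "ensemble")) {
  experiment <- match.arg(experiment)
  cfg <- list(
    experiment = experiment,
    contour = list(sigma = c(1, 2, 3), eps_unstable = 0.3,
                   eps_stable = NULL, slope = 0.65, growth = 1.05),
    grid = if (experiment == "2d-digits") list(resolution = c(20, 20))
           else list(n_x = 100, domain_length = 2 * pi),
    run = list(t_end = if (experiment == "ensemble") 60 else 160,
               dt = 0.05, rtol = 1e-8, atol = 1e-10),
    ensemble = list(n_trials = 60, ic_spread = 0.05, noise_sd = 0.005,
                    probe_sites = c(3, 21, 47, 88), seed = 1,
                    rejection_bound = NULL),
    export = list(prefix = "run", snapshot_stride = 40)
  )
  structure(cfg, class = "nf_config")
}

#' Load an experiment configuration from a flat text file
#'
#' Reads a YAML file of `key: value` pairs with nested blocks, fills in
#' defaults for omitted keys, and validates the result. Unknown keys are an
#' error (typo protection), as are invalid values (e.g. non-positive growth
#' rates).
#'
#' @param path configuration file. An empty file yields the full default
#'   configuration for the tag in `experiment`.
#' @param experiment default experiment tag when the file does not set one.
#' @return a validated `nf_config`.
#' @export
load_config <- function(path, experiment = "1d-sine") {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse error in ", path, ": ", conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  tag <- raw$experiment %||% experiment
  cfg <- unclass(default_config(tag))
  for (block in names(raw)) {
    if (block == "experiment") next
    if (!block %in% names(cfg))
      stop("unknown config block: `", block, "`")
    if (!is.list(raw[[block]]))
      stop("config block `", block, "` must be a mapping")
    for (key in names(raw[[block]])) {
      if (!key %in% names(cfg[[block]]))
        stop("unknown config key: `", block, ".", key, "`")
      cfg[[block]][key] <- list(raw[[block]][[key]])
    }
  }
  validate_config(structure(cfg, class = "nf_config"))
}

#' Save a configuration to a flat text file
#'
#' Inverse of [load_config()]; a save/load round trip is the identity.
#'
#' @param config an `nf_config`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  if (!cfg$experiment %in% c("1d-sine", "2d-digits", "ensemble"))
    stop("validation error: `experiment` must be 1d-sine, 2d-digits, ",
         "or ensemble")
  ctr <- cfg$contour
  if (any(ctr$sigma <= 0))
    stop("validation error: `contour.sigma` entries must be > 0")
  if (ctr$eps_unstable <= 0)
    stop("validation error: `contour.eps_unstable` must be > 0")
  run <- cfg$run
  if (run$t_end <= 0 || run$dt <= 0 || run$dt >= run$t_end)
    stop("validation error: `run.t_end` and `run.dt` must satisfy ",
         "0 < dt < t_end")
  ens <- cfg$ensemble
  if (ens$n_trials < 1) stop("validation error: `ensemble.n_trials` >= 1")
  if (ens$noise_sd < 0) stop("validation error: `ensemble.noise_sd` >= 0")
  if (cfg$experiment != "2d-digits") {
    if (cfg$grid$n_x < 2)
      stop("validation error: `grid.n_x` must be >= 2")
    if (any(ens$probe_sites < 1 | ens$probe_sites > cfg$grid$n_x))
      stop("validation error: `ensemble.probe_sites` outside the grid")
  }
  cfg
}

#' @export
print.nf_config <- function(x, ...) {
  cat("<nf_config> experiment:", x$experiment, "\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# internal: build the standard objects a config describes
setup_from_config <- function(cfg) {
  contour <- build_contour_matrix(cfg$contour$sigma,
                                  eps_unstable = cfg$contour$eps_unstable,
                                  eps_stable = cfg$contour$eps_stable,
                                  slope = cfg$contour$slope,
                                  growth = cfg$contour$growth)
  if (cfg$experiment == "2d-digits") {
    res <- cfg$grid$resolution
    pats <- lapply(1:3, function(d)
      downsample_pattern(render_digit(d, 5 * res[1L]), res))
    modes <- digits_to_modeset(pats)
    adjoints <- pseudoinverse_adjoints(modes)
  } else {
    grid <- make_grid_1d(cfg$grid$n_x, cfg$grid$domain_length)
    modes <- sine_modes(length(cfg$contour$sigma), grid)
    adjoints <- analytic_sine_adjoints(modes)
  }
  kernels <- build_kernels(modes, adjoints, contour)
  list(contour = contour, modes = modes, adjoints = adjoints,
       kernels = kernels)
}

#' Run a configured experiment end to end
#'
#' Orchestrates one of the three experiments: builds the contour, modes,
#' adjoints, and kernels, runs the simulations, writes the artifacts
#' (trajectory CSVs, probe traces, image snapshots) into `out_dir`, and
#' writes a JSON manifest echoing the configuration together with the
#' internal consistency checks (contour verification, order-parameter
#' equivalence error, dominance overlap, ensemble summary).
#'
#' @param config an `nf_config` (see [default_config()], [load_config()]).
#' @param out_dir output directory, created if needed.
#' @return the manifest, invisibly, with element `checks_passed` indicating
#'   whether every internal invariant check succeeded.
#' @export
run_experiment <- function(config, out_dir = "nf-run") {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  setup <- setup_from_config(cfg)
  prefix <- file.path(out_dir, cfg$export$prefix)
  run <- cfg$run
  manifest <- list(experiment = cfg$experiment,
                   config = unclass(cfg),
                   package_version = as.character(
                     utils::packageVersion("neurofield")))
  chk <- verify_contour(setup$contour)
  manifest$contour_check <- list(ok = chk$ok,
                                 eigenvalues = chk$eigenvalues)
  checks <- chk$ok

  if (cfg$experiment %in% c("1d-sine", "2d-digits")) {
    lv <- simulate_lv(setup$contour, t_end = run$t_end, dt = run$dt,
                      rtol = run$rtol, atol = run$atol)
    prescribed <- reconstruct_from_orders(lv, setup$modes)
    traj <- simulate_field(prescribed$states[1L, ], setup$kernels,
                           t_end = run$t_end, dt = run$dt,
                           rtol = run$rtol, atol = run$atol)
    err <- trajectory_error(prescribed, traj)
    alpha_hat <- project_onto_modes(traj, setup$adjoints)
    ws <- winner_sequence(alpha_hat, times = traj$times)
    manifest$order_parameter_error <- err
    manifest$winner_sequence <- ws
    manifest$solver_ok <- traj$diagnostics$ok
    checks <- checks && traj$diagnostics$ok && err < 1e-2
    write_lv_csv(lv, paste0(prefix, "_lv.csv"))
    write_field_csv(traj, paste0(prefix, "_field.csv"),
                    stride = cfg$export$snapshot_stride)
    if (cfg$experiment == "2d-digits") {
      probes <- select_probe_points(setup$modes)
      jac <- probe_dominance_jaccard(traj, setup$modes, probes, ws)
      manifest$probe_sites <- as.integer(probes)
      manifest$probe_jaccard <- jac
      checks <- checks && all(jac > 0.8)
      res <- cfg$grid$resolution
      for (k in seq_len(setup$modes$n)) {
        pat <- attr(setup$modes, "patterns")[[k]]
        write_pgm(pat$pixels, sprintf("%s_pattern%d.pgm", prefix, k))
        df <- data.frame(time = traj$times,
                         value = traj$states[, probes[k]])
        write_csv_full(df, sprintf("%s_probe%d.csv", prefix, k))
      }
      snaps <- seq(1L, length(traj$times),
                   by = cfg$export$snapshot_stride)
      for (s in snaps) {
        img <- matrix(traj$states[s, ], res[1L], res[2L], byrow = TRUE)
        rng <- max(abs(img), 1e-12)
        write_pgm((img / rng + 1) / 2,
                  sprintf("%s_snapshot_t%07.2f.pgm", prefix,
                          traj$times[s]))
      }
    }
  } else {
    ecfg <- do.call(ensemble_config, cfg$ensemble)
    ens <- run_ensemble(ecfg, setup$kernels, t_end = run$t_end,
                        dt = run$dt, rtol = run$rtol, atol = run$atol)
    early <- c(0, run$t_end / 10)
    late <- c(2 * run$t_end / 3, run$t_end)
    manifest$accepted <- sum(ens$accepted)
    manifest$rejected <- sum(!ens$accepted)
    manifest$rejection_reasons <- ens$reasons[!ens$accepted]
    manifest$decoherence_early <- decoherence_index(ens, early)
    manifest$decoherence_late <- decoherence_index(ens, late)
    manifest$grand_average_rms_first_third <-
      window_rms(ens$times, ens$grand_average, c(0, run$t_end / 3))
    manifest$grand_average_rms_final_third <-
      window_rms(ens$times, ens$grand_average, late)
    manifest$noise_recovered_sd <- noise_recovery(ens)
    checks <- checks &&
      all(manifest$decoherence_late > manifest$decoherence_early) &&
      manifest$grand_average_rms_final_third <
        manifest$grand_average_rms_first_third
    write_ensemble_csv(ens, prefix)
  }
  manifest$checks_passed <- checks
  jsonlite::write_json(manifest, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, dataframe = "columns",
                       matrix = "rowmajor")
  invisible(manifest)
}
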
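#' Configuration of a synthetic ERP trial ensemble
#'
#' Bundles the parameters of the trial-to-trial variability experiment:
#' repeated field simulations from randomized initial conditions near the
#' first saddle, recorded at a few "electrode" nodes with additive Gaussian
#' observational noise.
#'
#' @param n_trials number of trials (default 60).
#' @param ic_spread standard deviation of the random mode-coefficient
#'   perturbations around the first saddle (default 0.05).
#' @param noise_sd standard deviation of the observational noise added to
#'   the recorded probe traces (default 0.005). The noise never feeds back
#'   into the dynamics.
#' @param probe_sites 1-based grid node indices of the recording sites
#'   (default 3, 21, 47, 88 on the 100-node 1D grid).
#' @param seed integer RNG seed; ensembles are bit-reproducible given the
#'   seed.
#' @param rejection_bound trials whose field magnitude exceeds this bound
#'   are flagged rejected; `NULL` (default) resolves at run time to 10 times
#'   the largest saddle amplitude `max_k max_i |v_k(x_i)|`.
#' @return An object of class `nf_ensemble_config` (a validated list).
#' @export
ensemble_config <- function(n_trials = 60, ic_spread = 0.05,
                            noise_sd = 0.005,
                            probe_sites = c(3, 21, 47, 88),
                            seed = 1L, rejection_bound = NULL) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (ic_spread < 0) stop("`ic_spread` must be >= 0")
  structure(list(n_trials = as.integer(n_trials), ic_spread = ic_spread,
                 noise_sd = noise_sd, probe_sites = as.integer(probe_sites),
                 seed = as.integer(seed), rejection_bound = rejection_bound),
            class = "nf_ensemble_config")
}

#' Sample randomized initial field states near the first saddle
#'
#' Each trial starts at `u0 = v_1 + sum_k eta_k v_k`, an in-span
#' perturbation of the first metastable state (in-span so the
#' order-parameter reduction remains exact). The resident coefficient is
#' perturbed symmetrically, `eta_1 ~ N(0, ic_spread)`; the transverse
#' coefficients use the magnitude of a Gaussian,
#' `eta_k = |N(0, ic_spread)|` for `k >= 2`, keeping every population
#' activity nonnegative — a negative transverse coefficient lies in the
#' invariant negative region of the Lotka-Volterra flow and escapes to
#' infinity in finite time rather than following the contour.
#'
#' Uses the current RNG state; callers wanting reproducibility should seed
#' first (as [run_ensemble()] does).
#'
#' @param config an `nf_ensemble_config`.
#' @param modes the prescribed `nf_modes`.
#' @return list of `n_trials` initial field state vectors.
#' @export
sample_initial_conditions <- function(config, modes) {
  n <- modes$n
  lapply(seq_len(config$n_trials), function(i) {
    eta <- stats::rnorm(n, sd = config$ic_spread)
    if (n > 1L) eta[-1L] <- abs(eta[-1L])
    alpha0 <- eta
    alpha0[1L] <- alpha0[1L] + 1
    as.vector(alpha0 %*% modes$values)
  })
}

#' Run a synthetic ERP trial ensemble
#'
#' Simulates `n_trials` field trajectories from randomized initial
#' conditions, records the clean traces at the probe sites, adds Gaussian
#' observational noise to the recordings (observation only; the dynamics
#' stay deterministic), flags trials that fail the solver or exceed the
#' rejection bound, and computes the grand average over accepted trials.
#'
#' @param config an `nf_ensemble_config`.
#' @param kernels an `nf_kernels` defining the field dynamics.
#' @param t_end trial duration in ticks (default 60).
#' @param dt output sampling interval.
#' @param rtol,atol solver tolerances.
#' @return An object of class `nf_ensemble`: `times`, `probe_sites`,
#'   `clean` and `noisy` (lists of time x n_probes matrices, one per trial),
#'   `accepted` (logical), `reasons` (character, `""` for accepted trials),
#'   `grand_average` (time x n_probes mean of accepted noisy traces), and
#'   the `config` echo. Errors if every trial is rejected.
#' @export
run_ensemble <- function(config, kernels, t_end = 60, dt = 0.05,
                         rtol = 1e-8, atol = 1e-10) {
  modes <- kernels$modes
  if (any(config$probe_sites < 1L | config$probe_sites > modes$grid$n_x))
    stop("probe sites outside the grid")
  bound <- config$rejection_bound %||% (10 * max(abs(modes$values)))
  set.seed(config$seed)
  u0s <- sample_initial_conditions(config, modes)
  times <- seq(0, t_end, by = dt)
  n_p <- length(config$probe_sites)
  clean <- noisy <- vector("list", config$n_trials)
  accepted <- logical(config$n_trials)
  reasons <- character(config$n_trials)
  for (i in seq_len(config$n_trials)) {
    traj <- simulate_field(u0s[[i]], kernels, t_end = t_end, dt = dt,
                           rtol = rtol, atol = atol)
    tr_clean <- matrix(NA_real_, length(times), n_p)
    got <- nrow(traj$states)
    tr_clean[seq_len(got), ] <- traj$states[, config$probe_sites,
                                            drop = FALSE]
    if (!traj$diagnostics$ok) {
      accepted[i] <- FALSE
      reasons[i] <- paste0("solver failure: ", traj$diagnostics$message)
    } else if (max(abs(traj$states)) > bound) {
      accepted[i] <- FALSE
      reasons[i] <- sprintf("magnitude %.3g exceeded rejection bound %.3g",
                            max(abs(traj$states)), bound)
    } else {
      accepted[i] <- TRUE
    }
    clean[[i]] <- tr_clean
    noisy[[i]] <- tr_clean +
      matrix(stats::rnorm(length(tr_clean), sd = config$noise_sd),
             nrow(tr_clean), n_p)
  }
  if (!any(accepted))
    stop("empty ensemble: all ", config$n_trials, " trials were rejected (",
         reasons[1L], ")")
  ens <- structure(list(times = times, probe_sites = config$probe_sites,
                        clean = clean, noisy = noisy, accepted = accepted,
                        reasons = reasons, config = config,
                        rejection_bound = bound),
                   class = "nf_ensemble")
  ens$grand_average <- grand_average(ens)
  ens
}

#' @export
print.nf_ensemble <- function(x, ...) {
  cat("<nf_ensemble> ", length(x$accepted), " trials (", sum(x$accepted),
      " accepted, ", sum(!x$accepted), " rejected), ",
      length(x$probe_sites), " probes, t in [0, ",
      format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' Grand average of an ensemble
#'
#' Pointwise mean of the recorded (noisy) probe traces over accepted trials
#' only — the simulated analogue of the ERP grand average.
#'
#' @param ensemble an `nf_ensemble`.
#' @return numeric matrix, time x n_probes.
#' @export
grand_average <- function(ensemble) {
  acc <- which(ensemble$accepted)
  if (!length(acc)) stop("empty ensemble: no accepted trials")
  Reduce(`+`, ensemble$noisy[acc]) / length(acc)
}

#' Across-trial decoherence index
#'
#' For each probe site, the across-trial standard deviation of the clean
#' traces, averaged over a time window — a direct measure of the phase
#' dispersion that attenuates the grand average as trials desynchronize
#' along the heteroclinic contour.
#'
#' @param ensemble an `nf_ensemble`.
#' @param window numeric length-2 vector `c(from, to)` within the simulated
#'   time range.
#' @return numeric vector, one index per probe site (0 for identical
#'   trials; invariant under permuting trial labels).
#' @export
decoherence_index <- function(ensemble, window) {
  if (length(window) != 2L || window[1L] >= window[2L] ||
      window[1L] < min(ensemble$times) || window[2L] > max(ensemble$times))
    stop("bad window: need c(from, to) inside the simulated time range")
  sel <- ensemble$times >= window[1L] & ensemble$times <= window[2L]
  acc <- which(ensemble$accepted)
  if (length(acc) < 2L) return(rep(0, length(ensemble$probe_sites)))
  vapply(seq_along(ensemble$probe_sites), function(p) {
    tr <- vapply(acc, function(i) ensemble$clean[[i]][sel, p],
                 numeric(sum(sel)))          # time x trial
    mean(apply(tr, 1L, stats::sd))
  }, numeric(1L))
}

#' Recover the observational noise level from an ensemble
#'
#' Pools the residuals (noisy minus clean trace) over all probes, time
#' points, and accepted trials and returns their sample standard deviation —
#' an estimator of the injected observational noise level.
#'
#' @param ensemble an `nf_ensemble`.
#' @return a scalar estimate of the noise standard deviation.
#' @export
noise_recovery <- function(ensemble) {
  acc <- which(ensemble$accepted)
  res <- unlist(lapply(acc, function(i)
    ensemble$noisy[[i]] - ensemble$clean[[i]]))
  stats::sd(res[is.finite(res)])
}
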
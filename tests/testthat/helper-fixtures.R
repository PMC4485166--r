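# Shared fixtures, built once per test run and cached: the default study
# conditions (sigma = (1,2,3), 100-node 1D grid, 20x20 digit grid, 60-trial
# ensemble) are reused by several test files.
nf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = nf_cache, inherits = FALSE))
    assign(key, expr, envir = nf_cache)
  get(key, envir = nf_cache, inherits = FALSE)
}

fx_contour <- function() cached("contour", build_contour_matrix(c(1, 2, 3)))

fx_grid <- function() cached("grid", make_grid_1d(100))

fx_modes <- function() cached("modes", sine_modes(3, fx_grid()))

fx_adjoints <- function() cached("adjoints",
                                 analytic_sine_adjoints(fx_modes()))

fx_kernels <- function() cached("kernels",
  build_kernels(fx_modes(), fx_adjoints(), fx_contour()))

# default 1D experiment: LV run, prescribed surface, field simulation,
# projected amplitudes
fx_run_1d <- function() cached("run_1d", {
  lv <- simulate_lv(fx_contour(), t_end = 160)
  prescribed <- reconstruct_from_orders(lv, fx_modes())
  field <- simulate_field(prescribed$states[1L, ], fx_kernels(),
                          t_end = 160)
  list(lv = lv, prescribed = prescribed, field = field,
       alpha_hat = project_onto_modes(field, fx_adjoints()))
})

# default trial ensemble (60 trials, observational noise 0.005)
fx_ensemble <- function() cached("ensemble",
  run_ensemble(ensemble_config(seed = 42L), fx_kernels(), t_end = 60))

# default 2D digit experiment
fx_digits <- function() cached("digits", {
  pats <- lapply(1:3, function(d)
    downsample_pattern(render_digit(d, 100), c(20, 20)))
  modes <- digits_to_modeset(pats)
  adjoints <- pseudoinverse_adjoints(modes)
  list(patterns = pats, modes = modes, adjoints = adjoints,
       probes = select_probe_points(modes),
       kernels = build_kernels(modes, adjoints, fx_contour()))
})

fx_run_2d <- function() cached("run_2d", {
  d <- fx_digits()
  lv <- simulate_lv(fx_contour(), t_end = 160)
  field <- simulate_field(
    reconstruct_from_orders(lv, d$modes)$states[1L, ], d$kernels,
    t_end = 160)
  alpha_hat <- project_onto_modes(field, d$adjoints)
  list(lv = lv, field = field, alpha_hat = alpha_hat,
       ws = winner_sequence(alpha_hat, times = field$times))
})
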
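# Synthetic ERP trial ensembles: variability, averaging, decoherence

test_that("initial-condition sampler is in-span, keeps transverse
           coefficients nonnegative, and has the half-normal mean", {
  cfg <- ensemble_config(n_trials = 4000, ic_spread = 0.05)
  set.seed(123)
  u0s <- sample_initial_conditions(cfg, fx_modes())
  expect_length(u0s, 4000)
  alpha0 <- t(vapply(u0s, function(u)
    as.vector(fx_adjoints()$values %*% (fx_grid()$weights * u)),
    numeric(3)))
  expect_true(all(alpha0[, 2:3] >= 0))
  mc_tol <- 4 * 0.05 / sqrt(4000)     # four standard errors, absolute
  expect_lt(abs(mean(alpha0[, 1]) - 1), mc_tol)
  half_normal_mean <- 0.05 * sqrt(2 / pi)
  expect_lt(abs(mean(alpha0[, 2]) - half_normal_mean), mc_tol)
  expect_lt(abs(mean(alpha0[, 3]) - half_normal_mean), mc_tol)

  # zero spread: every trial starts exactly at the first mode
  set.seed(1)
  u0z <- sample_initial_conditions(
    ensemble_config(n_trials = 3, ic_spread = 0), fx_modes())
  for (u in u0z) expect_equal(u, fx_modes()$values[1, ])
})

test_that("ensembles are bit-reproducible under a fixed seed", {
  cfg <- ensemble_config(n_trials = 4, seed = 99L)
  e1 <- run_ensemble(cfg, fx_kernels(), t_end = 10)
  e2 <- run_ensemble(cfg, fx_kernels(), t_end = 10)
  expect_identical(e1$noisy, e2$noisy)
  expect_identical(e1$accepted, e2$accepted)
  expect_identical(e1$grand_average, e2$grand_average)
})

test_that("observational noise never feeds back into the dynamics", {
  base <- ensemble_config(n_trials = 3, seed = 5L, noise_sd = 0)
  loud <- ensemble_config(n_trials = 3, seed = 5L, noise_sd = 0.5)
  e0 <- run_ensemble(base, fx_kernels(), t_end = 10)
  e1 <- run_ensemble(loud, fx_kernels(), t_end = 10)
  expect_identical(e0$clean, e1$clean)
  expect_false(identical(e0$noisy, e1$noisy))
})

test_that("deterministic noiseless ensemble: identical trials, grand
           average equals any trial, zero decoherence", {
  cfg <- ensemble_config(n_trials = 3, ic_spread = 0, noise_sd = 0,
                         seed = 2L)
  ens <- run_ensemble(cfg, fx_kernels(), t_end = 10)
  expect_true(all(ens$accepted))
  expect_identical(ens$clean[[1]], ens$clean[[2]])
  expect_equal(ens$grand_average, ens$noisy[[1]])
  expect_equal(decoherence_index(ens, c(2, 8)), rep(0, 4))
})

test_that("decoherence index is invariant under permuting trial labels", {
  ens <- fx_ensemble()
  idx <- decoherence_index(ens, c(40, 60))
  perm <- sample(seq_along(ens$accepted))
  shuffled <- ens
  shuffled$clean <- ens$clean[perm]
  shuffled$noisy <- ens$noisy[perm]
  shuffled$accepted <- ens$accepted[perm]
  expect_equal(decoherence_index(shuffled, c(40, 60)), idx)
  expect_error(decoherence_index(ens, c(50, 40)), "window")
  expect_error(decoherence_index(ens, c(0, 1e6)), "window")
})

test_that("grand average is smoother than the single noisy trials", {
  ens <- fx_ensemble()
  msd <- function(x) mean(diff(x)^2)
  for (p in seq_along(ens$probe_sites)) {
    trial_msd <- vapply(which(ens$accepted),
                        function(i) msd(ens$noisy[[i]][, p]), numeric(1))
    expect_lt(msd(ens$grand_average[, p]), stats::median(trial_msd))
  }
})

test_that("trials beyond the rejection bound are rejected; an empty
           ensemble errors", {
  cfg <- ensemble_config(n_trials = 3, seed = 8L, rejection_bound = 0.5)
  expect_error(run_ensemble(cfg, fx_kernels(), t_end = 5),
               "empty ensemble")
})
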
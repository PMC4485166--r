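# Expanded Amari field dynamics and order-parameter reduction

test_that("field right-hand side vanishes at zero and at every prescribed
           mode", {
  ker <- fx_kernels()
  expect_equal(field_rhs(rep(0, 100), ker), rep(0, 100))
  for (k in 1:3)
    expect_lt(max(abs(field_rhs(fx_modes()$values[k, ], ker))), 1e-10)
  expect_error(field_rhs(rep(0, 7), ker), "dimension")
})

test_that("states orthogonal to all adjoints decay at unit rate", {
  ker <- fx_kernels()
  m <- fx_modes(); a <- fx_adjoints(); w <- fx_grid()$weights
  set.seed(9)
  gvec <- rnorm(100)
  # remove the in-span part: projections then vanish
  p <- as.vector(a$values %*% (w * gvec))
  gperp <- gvec - as.vector(t(m$values) %*% p)
  expect_lt(max(abs(a$values %*% (w * gperp))), 1e-10)
  expect_equal(field_rhs(gperp, ker), -gperp, tolerance = 1e-10)

  # closed form: the out-of-span component of u0 = v_1 + c*gperp decays
  # as c * exp(-t) * gperp while the in-span part stays at the saddle
  u0 <- m$values[1, ] + 0.5 * gperp
  traj <- simulate_field(u0, ker, t_end = 3, dt = 0.5)
  expect_true(traj$diagnostics$ok)
  for (i in seq_along(traj$times)) {
    inspan <- as.vector(
      t(m$values) %*% (a$values %*% (w * traj$states[i, ])))
    out <- traj$states[i, ] - inspan
    expect_equal(out, 0.5 * exp(-traj$times[i]) * gperp,
                 tolerance = 1e-5)
  }
})

test_that("a mode is a stationary solution of the field equation", {
  traj <- simulate_field(fx_modes()$values[1, ], fx_kernels(),
                         t_end = 5, dt = 0.5)
  expect_true(traj$diagnostics$ok)
  drift <- sweep(traj$states, 2, fx_modes()$values[1, ])
  expect_lt(max(abs(drift)), 1e-6)
})

test_that("reconstruction and projection are exact inverses", {
  run <- fx_run_1d()
  alpha <- project_onto_modes(run$prescribed, fx_adjoints())
  expect_equal(alpha, run$lv$alpha, tolerance = 1e-10)

  # constant alpha = e_1 reconstructs the first mode
  lv1 <- simulate_lv(fx_contour(), xi0 = saddle_state(1, fx_contour()),
                     t_end = 2, dt = 1)
  rec <- reconstruct_from_orders(lv1, fx_modes())
  expect_equal(rec$states[3, ], fx_modes()$values[1, ], tolerance = 1e-7)

  # a pure mode projects to a unit coordinate vector
  ahat <- project_onto_modes(rbind(fx_modes()$values[2, ]),
                             fx_adjoints())
  expect_equal(as.vector(ahat), c(0, 1, 0), tolerance = 1e-12)

  # projection ignores out-of-span components
  set.seed(2)
  g <- rnorm(100)
  p <- as.vector(fx_adjoints()$values %*% (fx_grid()$weights * g))
  gperp <- g - as.vector(t(fx_modes()$values) %*% p)
  ahat2 <- project_onto_modes(rbind(fx_modes()$values[2, ] + gperp),
                              fx_adjoints())
  expect_equal(as.vector(ahat2), c(0, 1, 0), tolerance = 1e-10)
})

test_that("trajectory error metric: zero for identical inputs, 0.5 for a
           doubled trajectory, error on disjoint ranges", {
  run <- fx_run_1d()
  expect_equal(trajectory_error(run$field, run$field), 0)
  doubled <- run$prescribed
  doubled$states <- 2 * doubled$states
  expect_equal(trajectory_error(run$prescribed, doubled), 0.5,
               tolerance = 1e-12)
  shifted <- run$prescribed
  shifted$times <- shifted$times + 1000
  expect_error(trajectory_error(run$prescribed, shifted), "disjoint")
})

test_that("trajectory error resamples mismatched time grids by linear
           interpolation", {
  a <- fx_run_1d()$prescribed
  coarse <- list(times = a$times[seq(1, length(a$times), 4)],
                 states = a$states[seq(1, length(a$times), 4), ],
                 grid = a$grid,
                 diagnostics = list(ok = TRUE))
  class(coarse) <- "nf_field_traj"
  expect_lt(trajectory_error(a, coarse), 1e-3)
})

test_that("field simulation from an in-span start reproduces the
           prescribed order parameters", {
  ctr <- fx_contour()
  lv <- simulate_lv(ctr, t_end = 40)
  pres <- reconstruct_from_orders(lv, fx_modes())
  traj <- simulate_field(pres$states[1, ], fx_kernels(), t_end = 40)
  expect_true(traj$diagnostics$ok)
  ahat <- project_onto_modes(traj, fx_adjoints())
  expect_equal(ahat, lv$alpha, tolerance = 1e-4)
})

test_that("a blow-up is reported through diagnostics, never silently", {
  # a large negative resident coefficient escapes in finite time
  u0 <- as.vector(c(-5, 0, 0) %*% fx_modes()$values)
  traj <- simulate_field(u0, fx_kernels(), t_end = 60)
  expect_false(traj$diagnostics$ok)
  expect_match(traj$diagnostics$message, "solver|non-finite|stopped")
})
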
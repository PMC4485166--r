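# Lotka-Volterra heteroclinic contour design and integration

test_that("contour builder yields unit diagonal, positive weights, and the
           designed eigenvalues (numerical Jacobian oracle)", {
  ctr <- build_contour_matrix(c(1, 2, 3), eps_unstable = 0.3)
  expect_identical(diag(ctr$rho), rep(1, 3))
  expect_true(all(ctr$rho > 0))

  chk <- verify_contour(ctr)
  expect_true(chk$ok)
  expect_identical(chk$unstable_direction, c(2L, 3L, 1L))
  # unstable eigenvalue at saddle k is eps_u * sigma_k by design
  for (k in 1:3)
    expect_equal(chk$eigenvalues[ctr$succ[k], k], 0.3 * ctr$sigma[k])

  skip_if_not_installed("pracma")
  for (k in 1:3) {
    J <- pracma::jacobian(function(x) lv_vector_field(x, ctr),
                          saddle_state(k, ctr))
    expect_equal(sort(Re(eigen(J)$values)), sort(chk$eigenvalues[, k]),
                 tolerance = 1e-6)
  }
})

test_that("two-population contour with equal growth rates matches the
           closed-form entry", {
  ctr <- build_contour_matrix(c(1, 1), eps_unstable = 0.5)
  expect_equal(ctr$rho[2, 1], 0.5)
  expect_equal(ctr$rho[1, 2], 0.5)
  expect_true(verify_contour(ctr)$ok)
})

test_that("builder rejects invalid growth rates and over-large unstable
           eigenvalues, naming the offending entry", {
  expect_error(build_contour_matrix(c(1, -2, 3)), "sigma")
  expect_error(build_contour_matrix(numeric(0)), "sigma")
  # eps_u * sigma_3 = 1.5 >= sigma_1 = 1 makes rho[1, 3] non-positive
  expect_error(build_contour_matrix(c(1, 2, 3), eps_unstable = 0.5),
               "rho\\[1, 3\\]")
})

test_that("vector field vanishes at the origin and at every saddle, and
           matches a finite-difference oracle at random states", {
  ctr <- fx_contour()
  expect_identical(lv_vector_field(rep(0, 3), ctr), rep(0, 3))
  for (k in 1:3) {
    s <- saddle_state(k, ctr)
    expect_lt(sqrt(sum(lv_vector_field(s, ctr)^2)), 1e-12)
  }
  expect_error(lv_vector_field(c(1, 2), ctr), "dimension")

  # oracle: central difference of the integrated flow
  set.seed(11)
  h <- 1e-4
  for (rep in 1:5) {
    xi <- runif(3)
    flow <- function(tt) {
      deSolve::ode(xi, c(0, tt), function(t, x, p)
        list(lv_vector_field(x, ctr)), NULL,
        rtol = 1e-12, atol = 1e-14)[2L, -1L]
    }
    fd <- (flow(h) - flow(-h)) / (2 * h)
    expect_equal(unname(fd), lv_vector_field(xi, ctr), tolerance = 1e-6)
  }
})

test_that("saddle_state places sigma_k on axis k and rejects bad indices", {
  expect_identical(saddle_state(2, c(1, 2, 3)), c(0, 2, 0))
  expect_identical(saddle_state(1, c(1, 2, 3)), c(1, 0, 0))
  expect_error(saddle_state(4, c(1, 2, 3)), "out of range")
  expect_error(saddle_state(0, c(1, 2, 3)), "out of range")
})

test_that("verify_contour rejects degenerate and over-inhibited matrices", {
  deg <- as_contour(c(1, 1, 1), matrix(1, 3, 3))
  expect_false(verify_contour(deg)$ok)      # zero eigenvalues everywhere
  # symmetric strong inhibition: every transverse eigenvalue negative
  attract <- as_contour(c(1, 1, 1),
                        matrix(5, 3, 3) - diag(4, 3))
  chk <- verify_contour(attract)
  expect_false(chk$ok)
  expect_true(all(is.na(chk$unstable_direction)))
})

test_that("trajectory started exactly at a saddle stays there", {
  ctr <- fx_contour()
  lv <- simulate_lv(ctr, xi0 = saddle_state(1, ctr), t_end = 10)
  expect_true(lv$diagnostics$ok)
  expect_equal(max(abs(sweep(lv$xi, 2, saddle_state(1, ctr)))), 0,
               tolerance = 1e-7)
})

test_that("single population follows the logistic closed form", {
  ctr <- as_contour(3, matrix(1, 1, 1))
  lv <- simulate_lv(ctr, xi0 = 0.1, t_end = 6, dt = 0.1)
  closed <- 3 / (1 + (3 / 0.1 - 1) * exp(-3 * lv$times))
  expect_equal(as.vector(lv$xi), closed, tolerance = 1e-6)
  expect_equal(lv$xi[length(lv$times), 1], 3, tolerance = 1e-6)
})

test_that("amplitudes are the activities divided by the growth rates, and
           match the trajectory of the amplitude-rescaled system", {
  lv <- fx_run_1d()$lv
  expect_equal(lv$alpha, sweep(lv$xi, 2, lv$contour$sigma, "/"))

  # rescaled system: same growth rates, interactions scaled by sigma_j
  ctr <- fx_contour()
  resc <- as_contour(ctr$sigma, sweep(ctr$rho, 2, ctr$sigma, "*"))
  lv2 <- simulate_lv(resc, xi0 = lv$alpha[1, ], t_end = 40)
  keep <- seq_along(lv2$times)
  expect_equal(lv2$xi, lv$alpha[keep, ], tolerance = 1e-5)
})

test_that("nonnegative initial conditions stay nonnegative", {
  ctr <- fx_contour()
  set.seed(5)
  for (rep in 1:6) {
    lv <- simulate_lv(ctr, xi0 = runif(3), t_end = 30)
    expect_true(lv$diagnostics$ok)
    expect_gt(min(lv$xi), -1e-8)
  }
})

test_that("winner sequence: constant saddle trajectory is one dwell; the
           default run cycles 1-2-3 with per-cycle dwell ordering", {
  ctr <- fx_contour()
  const <- simulate_lv(ctr, xi0 = saddle_state(2, ctr), t_end = 10)
  ws <- winner_sequence(const)
  expect_identical(ws$mode, 2L)
  expect_equal(ws$t_on, 0)
  expect_equal(ws$t_off, 10)

  expect_error(winner_sequence(const, dominance_threshold = 1.2),
               "dominance_threshold")

  ws <- winner_sequence(fx_run_1d()$lv)
  # cyclic visiting order 1 -> 2 -> 3 -> 1 -> ...
  expect_identical(ws$mode, rep_len(c(1L, 2L, 3L), nrow(ws)))
  cyc <- dwell_cycles(ws)
  expect_gte(max(cyc$cycle), 2)
  for (ci in unique(cyc$cycle)[-1]) {
    d <- cyc$dwell[cyc$cycle == ci]
    expect_identical(cyc$mode[cyc$cycle == ci], c(1L, 2L, 3L))
    expect_true(all(diff(d) < 0))  # dwell(1) > dwell(2) > dwell(3)
  }
})

test_that("trajectory export carries the documented CSV header", {
  f <- withr::local_tempfile(fileext = ".csv")
  lv <- simulate_lv(fx_contour(), t_end = 1, dt = 0.5)
  write_lv_csv(lv, f)
  expect_identical(readLines(f, n = 1L),
                   "time,xi_1,xi_2,xi_3,alpha_1,alpha_2,alpha_3")
  back <- utils::read.csv(f)
  expect_equal(back$xi_2, lv$xi[, 2])
})
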
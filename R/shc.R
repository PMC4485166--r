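#' Design a Lotka-Volterra interaction matrix realizing a heteroclinic contour
#'
#' Constructs the interaction matrix `rho` of the generalized Lotka-Volterra
#' system
#' \deqn{d\xi_k/dt = \xi_k (\sigma_k - \sum_j \rho_{kj} \xi_j)}
#' so that the single-population saddles \eqn{S_k = \sigma_k e_k} form a
#' closed heteroclinic contour visited in cyclic order `1 -> 2 -> ... -> n -> 1`
#' under winnerless competition.
#'
#' The matrix is specified through the transverse eigenvalues at each saddle.
#' At \eqn{S_k} the linearization has eigenvalues
#' \eqn{\lambda_j = \sigma_j - \rho_{jk}\sigma_k} for \eqn{j \ne k} and the
#' longitudinal \eqn{\lambda_k = -\sigma_k}. The builder sets
#' \itemize{
#'   \item \eqn{\lambda_{succ(k)} = +\epsilon_u \sigma_k}: exactly one
#'     unstable direction, pointing to the successor, with escape rate
#'     proportional to the resident growth rate. Populations with larger
#'     growth rates are therefore left sooner, ordering the dwell times as
#'     \eqn{T_k \propto 1/\sigma_k}.
#'   \item \eqn{\lambda_j = -s_k} for the remaining transverse directions,
#'     where the per-saddle contraction rates \eqn{s_k} are derived from
#'     dwell-map slopes \eqn{a_k = s_k / \lambda_u(succ(k))}: by default
#'     \eqn{a_k = slope < 1} for `k < n` and
#'     \eqn{a_n = growth / slope^{n-1}}, so that successive dwell times
#'     within a cycle shrink while the total cycle slowly lengthens
#'     (`growth` slightly above 1 keeps the contour attracting).
#' }
#' Diagonal entries are exactly 1.
#'
#' @param sigma vector of strictly positive growth rates, length `n >= 2`.
#' @param eps_unstable positive scalar; unstable-eigenvalue scale. Must
#'   satisfy `eps_unstable * sigma[k] < sigma[succ(k)]` for every `k` so all
#'   interaction weights remain positive.
#' @param eps_stable optional explicit stable transverse rates: a positive
#'   scalar or length-`n` vector `s_k`. When `NULL` (default) the rates are
#'   derived from `slope` and `growth` as described above.
#' @param slope dwell-map slope for saddles `1..n-1` (default 0.65).
#' @param growth per-cycle dwell growth factor (default 1.05).
#' @return An object of class `nf_contour`: list with `sigma`, `rho`
#'   (`n x n`, positive, unit diagonal), `succ` (cyclic successor map), and
#'   the design parameters.
#' @examples
#' ctr <- build_contour_matrix(c(1, 2, 3))
#' diag(ctr$rho)            # all exactly 1
#' verify_contour(ctr)$ok   # TRUE
#' @export
build_contour_matrix <- function(sigma, eps_unstable = 0.3, eps_stable = NULL,
                                 slope = 0.65, growth = 1.05) {
  check_sigma(sigma)
  n <- length(sigma)
  if (!is.numeric(eps_unstable) || length(eps_unstable) != 1L ||
      eps_unstable <= 0)
    stop("`eps_unstable` must be a single positive number")
  succ <- c(seq_len(n)[-1L], 1L)
  lam_u <- eps_unstable * sigma          # unstable eigenvalue at each saddle
  bad <- which(lam_u >= sigma[succ])
  if (length(bad)) {
    k <- bad[1L]
    stop(sprintf(paste0(
      "constraint violation: eps_unstable = %g makes rho[%d, %d] = ",
      "(sigma[%d] - eps_unstable * sigma[%d]) / sigma[%d] non-positive; ",
      "need eps_unstable < %g"),
      eps_unstable, succ[k], k, succ[k], k, k, min(sigma[succ] / sigma)))
  }
  if (is.null(eps_stable)) {
    a <- c(rep(slope, n - 1L), growth / slope^(n - 1L))
    s <- a * lam_u[succ]
  } else {
    if (!is.numeric(eps_stable) || any(eps_stable <= 0) ||
        !(length(eps_stable) %in% c(1L, n)))
      stop("`eps_stable` must be a positive scalar or length-n vector")
    s <- rep_len(eps_stable, n)
  }
  rho <- diag(n)
  for (k in seq_len(n)) {
    for (j in seq_len(n)[-k]) {
      rho[j, k] <- if (j == succ[k]) (sigma[j] - lam_u[k]) / sigma[k]
                   else               (sigma[j] + s[k])    / sigma[k]
    }
  }
  structure(
    list(sigma = as.numeric(sigma), rho = rho, succ = succ,
         eps_unstable = eps_unstable, eps_stable = s,
         slope = slope, growth = growth),
    class = "nf_contour")
}

#' Wrap growth rates and an explicit interaction matrix
#'
#' Escape hatch for hand-specified Lotka-Volterra systems (e.g. degenerate or
#' non-contour matrices used to exercise [verify_contour()]).
#'
#' @param sigma positive growth rates.
#' @param rho `n x n` interaction matrix.
#' @param succ optional successor map; defaults to the cyclic order.
#' @return An `nf_contour` object.
#' @export
as_contour <- function(sigma, rho, succ = NULL) {
  check_sigma(sigma)
  n <- length(sigma)
  rho <- as.matrix(rho)
  if (!all(dim(rho) == n)) stop("`rho` must be an n x n matrix")
  if (is.null(succ)) succ <- c(seq_len(n)[-1L], 1L)
  structure(list(sigma = as.numeric(sigma), rho = rho, succ = as.integer(succ)),
            class = "nf_contour")
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) < 1L || any(!is.finite(sigma)) ||
      any(sigma <= 0))
    stop("invalid parameter: growth rates `sigma` must all be > 0")
  invisible(sigma)
}

#' @export
print.nf_contour <- function(x, ...) {
  n <- length(x$sigma)
  cat("<nf_contour> ", n, " populations, sigma = (",
      paste(format(x$sigma), collapse = ", "), ")\n", sep = "")
  cat("rho:\n"); print(round(x$rho, 4))
  invisible(x)
}

#' Lotka-Volterra vector field
#'
#' Right-hand side \eqn{\xi_k (\sigma_k - \sum_j \rho_{kj} \xi_j)} of the
#' population dynamics.
#'
#' @param xi state vector of population activities.
#' @param contour an `nf_contour` (see [build_contour_matrix()]).
#' @return the componentwise time derivative.
#' @export
lv_vector_field <- function(xi, contour) {
  sigma <- contour$sigma; rho <- contour$rho
  if (length(xi) != length(sigma))
    stop("dimension mismatch: length(xi) != length(sigma)")
  as.numeric(xi * (sigma - as.vector(rho %*% xi)))
}

# internal: Jacobian of the LV vector field at xi
lv_jacobian <- function(xi, contour) {
  sigma <- contour$sigma; rho <- contour$rho
  diag(as.vector(sigma - rho %*% xi), length(xi)) - xi * rho
}

#' Saddle equilibrium of the k-th population
#'
#' The single-population fixed point \eqn{S_k = \sigma_k e_k} (using
#' \eqn{\rho_{kk} = 1}), the metastable state the contour dwells at.
#'
#' @param k population index, `1 <= k <= n`.
#' @param contour an `nf_contour`, or a numeric vector of growth rates.
#' @return state vector with `sigma[k]` at position `k`, zeros elsewhere.
#' @export
saddle_state <- function(k, contour) {
  sigma <- if (inherits(contour, "nf_contour")) contour$sigma else contour
  check_sigma(sigma)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(sigma) ||
      k != round(k))
    stop("saddle index `k` out of range")
  xi <- numeric(length(sigma))
  xi[k] <- sigma[k]
  xi
}

#' Verify the saddle structure of a heteroclinic contour
#'
#' At each saddle \eqn{S_k} reports the closed-form eigenvalues of the
#' linearized flow (transverse \eqn{\lambda_j = \sigma_j - \rho_{jk}\sigma_k},
#' longitudinal \eqn{\lambda_k = -\sigma_k}) and checks that exactly one is
#' positive and that it points along the successor direction — the defining
#' condition of a stable heteroclinic contour through metastable states.
#'
#' @param contour an `nf_contour`.
#' @param tol eigenvalues with magnitude below `tol` count as zero
#'   (degenerate, fails the check).
#' @return An object of class `nf_contour_check`: list with per-saddle
#'   `eigenvalues` (n x n matrix, column k = eigenvalues at saddle k),
#'   `unstable_direction`, `saddle_ok` (logical per saddle), and overall `ok`.
#' @export
verify_contour <- function(contour, tol = 1e-10) {
  sigma <- contour$sigma; rho <- contour$rho; n <- length(sigma)
  succ <- contour$succ %||% c(seq_len(n)[-1L], 1L)
  ev <- matrix(0, n, n, dimnames = list(direction = NULL, saddle = NULL))
  unstable <- integer(n); ok <- logical(n)
  for (k in seq_len(n)) {
    lam <- sigma - rho[, k] * sigma[k]
    lam[k] <- -sigma[k]
    ev[, k] <- lam
    pos <- which(lam > tol)
    unstable[k] <- if (length(pos) == 1L) pos else NA_integer_
    ok[k] <- length(pos) == 1L && identical(pos, succ[k]) &&
      all(lam[-pos] < -tol)
  }
  structure(list(eigenvalues = ev, unstable_direction = unstable,
                 saddle_ok = ok, ok = all(ok)),
            class = "nf_contour_check")
}

#' @export
print.nf_contour_check <- function(x, ...) {
  n <- ncol(x$eigenvalues)
  cat("<nf_contour_check> ", if (x$ok) "PASS" else "FAIL", "\n", sep = "")
  for (k in seq_len(n))
    cat(sprintf("  saddle %d: eigenvalues (%s), unstable dir %s [%s]\n",
                k, paste(format(x$eigenvalues[, k], digits = 4),
                         collapse = ", "),
                ifelse(is.na(x$unstable_direction[k]), "-",
                       x$unstable_direction[k]),
                if (x$saddle_ok[k]) "ok" else "fail"))
  invisible(x)
}

#' Integrate the Lotka-Volterra population dynamics
#'
#' Solves the winnerless-competition system with a variable-order stiff
#' (backward-differentiation) method and returns both the activities
#' \eqn{\xi_k(t)} and the amplitudes \eqn{\alpha_k(t) = \xi_k(t) / \sigma_k}
#' that weight the spatial modes in the order-parameter expansion
#' (\eqn{\alpha_k = 1} when the contour sits at saddle k).
#'
#' @param contour an `nf_contour`.
#' @param xi0 nonnegative initial state. Default: the first saddle displaced
#'   by `delta` on components `2..n`, so the orbit leaves along the unstable
#'   direction of \eqn{S_1}.
#' @param t_end end time in dimensionless ticks.
#' @param dt output sampling interval.
#' @param delta displacement used by the default initial condition.
#' @param rtol,atol solver tolerances.
#' @return An object of class `nf_lv_traj`: `times`, `xi` (time x n),
#'   `alpha`, the `contour`, and `diagnostics` (`ok`, `message`). On solver
#'   failure the partial trajectory is returned with `diagnostics$ok = FALSE`;
#'   failure is never silent.
#' @export
simulate_lv <- function(contour, xi0 = NULL, t_end = 160, dt = 0.05,
                        delta = 1e-3, rtol = 1e-8, atol = 1e-10) {
  sigma <- contour$sigma; n <- length(sigma)
  if (is.null(xi0)) {
    xi0 <- saddle_state(1L, contour)
    if (n > 1L) xi0[-1L] <- delta
  }
  if (length(xi0) != n) stop("dimension mismatch: length(xi0) != n")
  if (any(xi0 < 0)) stop("initial state `xi0` must be componentwise >= 0")
  times <- seq(0, t_end, by = dt)
  rhs <- function(t, xi, p) list(lv_vector_field(xi, contour))
  jac <- function(t, xi, p) lv_jacobian(xi, contour)
  sol <- solve_checked(xi0, times, rhs, jac, rtol, atol)
  xi <- sol$states
  structure(list(times = sol$times, xi = xi,
                 alpha = sweep(xi, 2L, sigma, "/"),
                 contour = contour, diagnostics = sol$diagnostics),
            class = "nf_lv_traj")
}

#' @export
print.nf_lv_traj <- function(x, ...) {
  cat("<nf_lv_traj> ", ncol(x$xi), " populations, ", length(x$times),
      " time points over [", format(min(x$times)), ", ",
      format(max(x$times)), "]",
      if (!x$diagnostics$ok) "  [SOLVER FAILURE - partial]", "\n", sep = "")
  invisible(x)
}

# internal: run deSolve's bdf method, never fail silently
solve_checked <- function(y0, times, rhs, jac, rtol, atol) {
  wmsg <- NULL
  out <- tryCatch(
    withCallingHandlers(
      deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                   method = "bdf", rtol = rtol, atol = atol,
                   jacfunc = jac, jactype = "fullusr"),
      warning = function(w) {
        wmsg <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (inherits(out, "condition")) {
    return(list(times = times[1L],
                states = matrix(y0, nrow = 1L),
                diagnostics = list(ok = FALSE,
                                   message = paste("solver error:",
                                                   conditionMessage(out)))))
  }
  states <- unname(out[, -1L, drop = FALSE])
  ok <- nrow(out) == length(times) && all(is.finite(states)) &&
    is.null(wmsg)
  msg <- if (ok) "completed" else
    paste0("solver stopped after ", nrow(out), " of ", length(times),
           " output points",
           if (!is.null(wmsg)) paste0(" (", wmsg, ")"))
  if (!ok && any(!is.finite(states))) {
    keep <- which(apply(is.finite(states), 1L, all))
    keep <- seq_len(if (length(keep)) max(keep) else 1L)
    states <- states[keep, , drop = FALSE]
    out <- out[keep, , drop = FALSE]
    msg <- "non-finite values encountered; trajectory truncated"
  }
  list(times = unname(out[, 1L]), states = states,
       diagnostics = list(ok = ok, message = msg))
}

#' Winner-take-all dominance sequence of a trajectory
#'
#' Extracts the maximal time intervals during which a single mode amplitude
#' exceeds `dominance_threshold` while all others stay below it. Transients
#' between dwells (no dominant mode) appear as gaps.
#'
#' @param x an `nf_lv_traj`, or a numeric matrix of amplitudes (time x n)
#'   with the `times` argument supplied.
#' @param dominance_threshold dominance level on the amplitude scale
#'   (\eqn{\alpha = 1} at a saddle); must lie in (0, 1).
#' @param times time vector when `x` is a plain matrix.
#' @return A data frame with one row per dwell: `mode`, `t_on`, `t_off`,
#'   `dwell = t_off - t_on`, ordered in time.
#' @export
winner_sequence <- function(x, dominance_threshold = 0.9, times = NULL) {
  if (inherits(x, "nf_lv_traj")) {
    alpha <- x$alpha; times <- x$times
  } else {
    alpha <- as.matrix(x)
    if (is.null(times)) stop("`times` must be supplied for matrix input")
  }
  if (!is.numeric(dominance_threshold) || length(dominance_threshold) != 1L ||
      dominance_threshold <= 0 || dominance_threshold >= 1)
    stop("invalid parameter: `dominance_threshold` must lie in (0, 1)")
  if (nrow(alpha) == 0L) stop("empty trajectory")
  winner <- apply(alpha, 1L, function(a) {
    i <- which(a > dominance_threshold)
    if (length(i) == 1L && all(a[-i] <= dominance_threshold)) i else 0L
  })
  r <- rle(winner)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values > 0L)
  data.frame(mode = r$values[keep],
             t_on = times[starts[keep]],
             t_off = times[ends[keep]],
             dwell = times[ends[keep]] - times[starts[keep]])
}

#' Split a winner sequence into full contour cycles
#'
#' Groups consecutive dwells into cycles, each cycle starting at a visit of
#' mode 1 (the contour's reference saddle). Incomplete leading/trailing
#' segments are dropped.
#'
#' @param ws a winner-sequence data frame from [winner_sequence()].
#' @return the same data frame restricted to full cycles, with a `cycle`
#'   column added.
#' @export
dwell_cycles <- function(ws) {
  starts <- which(ws$mode == 1L)
  if (length(starts) < 2L)
    return(cbind(ws[0L, ], cycle = integer(0)))
  out <- NULL
  for (i in seq_len(length(starts) - 1L)) {
    seg <- ws[starts[i]:(starts[i + 1L] - 1L), , drop = FALSE]
    out <- rbind(out, cbind(seg, cycle = i))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
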
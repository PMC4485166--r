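#' Wrap sampled spatial patterns as a mode set
#'
#' A mode set holds `n` prescribed metastable spatial patterns `v_k(x)`
#' sampled on a grid, one row per mode. Rows must be linearly independent
#' (checked through the numerical rank of the weighted mode matrix; singular
#' values below `1e-10` times the largest count as zero).
#'
#' @param values numeric matrix, `n x N_x`, row k sampling `v_k`.
#' @param grid the `nf_grid` the rows are sampled on.
#' @param provenance optional tag recording how the modes were built.
#' @return An object of class `nf_modes`.
#' @export
modeset <- function(values, grid, provenance = "user") {
  values <- as.matrix(values)
  if (ncol(values) != grid$n_x)
    stop("mode matrix has ", ncol(values), " columns but grid has ",
         grid$n_x, " nodes")
  if (nrow(values) > grid$n_x)
    stop("cannot have more modes than grid nodes")
  r <- weighted_rank(values, grid$weights)
  if (r < nrow(values))
    stop("degenerate modes: numerical rank ", r, " < ", nrow(values),
         " rows; modes must be linearly independent")
  structure(list(values = values, grid = grid, n = nrow(values),
                 provenance = provenance),
            class = "nf_modes")
}

# internal: rank of V scaled by sqrt(weights), relative threshold 1e-10
weighted_rank <- function(values, weights, rel_tol = 1e-10) {
  sv <- svd(sweep(values, 2L, sqrt(weights), "*"), nu = 0L, nv = 0L)$d
  sum(sv > rel_tol * sv[1L])
}

#' @export
print.nf_modes <- function(x, ...) {
  cat("<nf_modes> ", x$n, " modes on ", x$grid$n_x, " nodes (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Sinusoidal modes on the periodic 1D domain
#'
#' The classic one-dimensional pattern family `v_k(x) = sin(k x)` on
#' `[0, 2*pi)`. On the half-open uniform grid these satisfy the discrete
#' orthogonality `sum_i sin(j x_i) sin(k x_i) w_i = pi * delta_jk` exactly
#' (for `j, k < N_x / 2`), mirroring the continuum relation.
#'
#' @param n number of modes; must satisfy `n < N_x / 2`.
#' @param grid a periodic 1D `nf_grid` of length `2*pi`.
#' @return An `nf_modes` with rows `sin(k * x_i)`.
#' @export
sine_modes <- function(n, grid = make_grid_1d(100)) {
  if (grid$topology != "periodic-1d")
    stop("sine modes require a periodic 1D grid")
  if (abs(grid$domain_length - 2 * pi) > 1e-12)
    stop("sine modes are defined on a domain of length 2*pi")
  if (n >= grid$n_x / 2)
    stop("need n < N_x / 2 for distinct sine modes")
  vals <- t(vapply(seq_len(n), function(k) sin(k * grid$coords),
                   numeric(grid$n_x)))
  modeset(vals, grid, provenance = "sine")
}

#' Adjoint set constructor (internal representation)
#' @noRd
adjointset <- function(values, grid, provenance = "user") {
  structure(list(values = as.matrix(values), grid = grid,
                 n = nrow(values), provenance = provenance),
            class = "nf_adjoints")
}

#' @export
print.nf_adjoints <- function(x, ...) {
  cat("<nf_adjoints> ", x$n, " adjoints on ", x$grid$n_x, " nodes (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Analytic adjoints of the sine modes
#'
#' For the sine family the biorthogonal adjoints are available in closed
#' form, `v_k^+(x) = sin(k x) / pi`, because the modes are orthogonal with
#' self-inner product `pi` under the quadrature.
#'
#' @param modes an `nf_modes` produced by [sine_modes()].
#' @return An `nf_adjoints` satisfying the weighted biorthogonality
#'   `sum_i v_j^+(x_i) v_k(x_i) w_i = delta_jk`.
#' @export
analytic_sine_adjoints <- function(modes) {
  if (!inherits(modes, "nf_modes") || modes$provenance != "sine")
    stop("analytic adjoints are only defined for sine_modes() output")
  adjointset(modes$values / pi, modes$grid, provenance = "analytic-sine")
}

#' Biorthogonal adjoints via the weighted Moore-Penrose pseudoinverse
#'
#' Computes the unique adjoint set that satisfies the weighted
#' biorthogonality `A W V' = I` (`W` the diagonal quadrature-weight matrix)
#' with every adjoint row in the span of the mode rows (the minimum-norm
#' property of the pseudoinverse): `A = (V W V')^{-1} V`.
#'
#' @param modes an `nf_modes` with linearly independent rows.
#' @return An `nf_adjoints`.
#' @export
pseudoinverse_adjoints <- function(modes) {
  V <- modes$values; w <- modes$grid$weights
  r <- weighted_rank(V, w)
  if (r < nrow(V))
    stop("degenerate modes: numerical rank ", r, " < ", nrow(V), " rows")
  G <- V %*% (w * t(V))          # weighted Gram matrix, n x n
  A <- solve(G, V)
  adjointset(A, modes$grid, provenance = "pseudoinverse")
}

#' Maximum deviation from biorthogonality
#'
#' Evaluates `max_jk | sum_i v_j^+(x_i) v_k(x_i) w_i - delta_jk |`, the
#' discrete residual of the continuum biorthogonality relation.
#'
#' @param modes an `nf_modes`.
#' @param adjoints an `nf_adjoints` on the same grid.
#' @return a nonnegative scalar.
#' @export
check_biorthogonality <- function(modes, adjoints) {
  if (!same_grid(modes$grid, adjoints$grid) || modes$n != adjoints$n)
    stop("modes and adjoints must share grid and mode count")
  G <- adjoints$values %*% (modes$grid$weights * t(modes$values))
  max(abs(G - diag(modes$n)))
}
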
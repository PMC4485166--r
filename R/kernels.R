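#' Build the Pincherle-Goursat synaptic kernels
#'
#' Assembles the two-point and three-point kernels of the expanded field
#' equation from the prescribed modes, their adjoints, and the
#' Lotka-Volterra parameters:
#' \deqn{w_1(x, y) = \sum_k (\sigma_k + 1) v_k(x) v_k^+(y)}
#' \deqn{w_2(x, y, z) = -\sum_{kj} \sigma_j \rho_{kj} v_k(x) v_k^+(y) v_j^+(z)}
#' Because both kernels are finite-rank (separable) in the modes, the
#' factored representation — coefficients `c1_k = sigma_k + 1` and
#' `c2_kj = -sigma_j * rho_kj` alongside the mode and adjoint matrices — is
#' exact, not an approximation, and is the default. Dense tensors are only
#' materialized on request and for small grids: the three-point tensor has
#' `N_x^3` entries and is refused beyond `memory_budget` nodes.
#'
#' @param modes an `nf_modes` (the prescribed metastable patterns).
#' @param adjoints matching `nf_adjoints` (see [pseudoinverse_adjoints()]).
#' @param contour an `nf_contour` carrying `sigma` and `rho`.
#' @param representation `"factored"` (default) or `"dense"`.
#' @param memory_budget maximum `N_x` for which dense tensors are built
#'   (default 150, about 27 MB for the rank-3 tensor).
#' @return An object of class `nf_kernels`. Factored: fields `modes`,
#'   `adjoints`, `c1` (length n), `c2` (n x n). Dense: additionally `W1`
#'   (`N_x x N_x`) and `W2` (`N_x x N_x x N_x`).
#' @examples
#' g <- make_grid_1d(16)
#' m <- sine_modes(3, g)
#' ker <- build_kernels(m, analytic_sine_adjoints(m), build_contour_matrix(1:3))
#' @export
build_kernels <- function(modes, adjoints, contour,
                          representation = c("factored", "dense"),
                          memory_budget = 150) {
  representation <- match.arg(representation)
  sigma <- contour$sigma; rho <- contour$rho
  n <- length(sigma)
  if (modes$n != n || adjoints$n != n)
    stop("mode count must match the number of Lotka-Volterra populations")
  if (!same_grid(modes$grid, adjoints$grid))
    stop("modes and adjoints must live on the same grid")
  c1 <- sigma + 1
  c2 <- -sweep(rho, 2L, sigma, "*")    # c2[k, j] = -sigma_j * rho_kj
  ker <- list(representation = representation, modes = modes,
              adjoints = adjoints, contour = contour, c1 = c1, c2 = c2)
  if (representation == "dense") {
    n_x <- modes$grid$n_x
    if (n_x > memory_budget)
      stop("dense three-point kernel needs N_x^3 = ", n_x, "^3 entries, ",
           "over the memory budget (N_x <= ", memory_budget, "); ",
           "use representation = \"factored\" (exact for these kernels)")
    V <- modes$values; A <- adjoints$values
    ker$W1 <- t(V) %*% (c1 * A)
    W2 <- array(0, dim = c(n_x, n_x, n_x))
    for (k in seq_len(n)) for (j in seq_len(n)) {
      W2 <- W2 + c2[k, j] * outer(outer(V[k, ], A[k, ]), A[j, ])
    }
    ker$W2 <- W2
  }
  structure(ker, class = "nf_kernels")
}

#' @export
print.nf_kernels <- function(x, ...) {
  cat("<nf_kernels> ", x$representation, " Pincherle-Goursat pair, rank ",
      x$modes$n, " on ", x$modes$grid$n_x, " nodes\n", sep = "")
  invisible(x)
}

#' Right-hand side of the expanded Amari field equation
#'
#' Evaluates
#' \deqn{-u + \int w_1(x,y) u(y) dy + \int\int w_2(x,y,z) u(y) u(z) dy dz}
#' on the grid (integrals are quadrature-weighted sums). The factored path
#' computes the adjoint projections `p_k = sum_i v_k^+(x_i) u_i w_i` and then
#' `-u + V' (c1 * p + p * (c2 p))`; the dense path contracts the stored
#' tensors. Both agree to rounding error.
#'
#' @param u field state vector (length `N_x`).
#' @param kernels an `nf_kernels`.
#' @return the time derivative of the field, a vector of length `N_x`.
#' @export
field_rhs <- function(u, kernels) {
  grid <- kernels$modes$grid
  if (length(u) != grid$n_x)
    stop("dimension mismatch: length(u) != N_x")
  if (kernels$representation == "dense") {
    wu <- grid$weights * u
    lin <- as.vector(kernels$W1 %*% wu)
    quad <- as.vector(apply(kernels$W2, 1L, function(s) wu %*% s %*% wu))
    return(-u + lin + quad)
  }
  p <- as.vector(kernels$adjoints$values %*% (grid$weights * u))
  coef <- kernels$c1 * p + p * as.vector(kernels$c2 %*% p)
  -u + as.vector(t(kernels$modes$values) %*% coef)
}

# internal: Jacobian of field_rhs (always via the factored structure)
field_jacobian <- function(u, kernels) {
  grid <- kernels$modes$grid
  A <- kernels$adjoints$values; V <- kernels$modes$values
  AW <- sweep(A, 2L, grid$weights, "*")
  p <- as.vector(AW %*% u)
  Dk <- diag(kernels$c1, length(p)) +
    diag(as.vector(kernels$c2 %*% p), length(p)) + p * kernels$c2
  -diag(grid$n_x) + t(V) %*% Dk %*% AW
}
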
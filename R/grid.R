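#' Uniform periodic grid on a one-dimensional domain
#'
#' Discretizes the interval `[0, domain_length)` with `n_x` equally spaced
#' nodes `x_i = i * domain_length / n_x`, `i = 0, ..., n_x - 1` (half-open
#' convention: the right endpoint is identified with the left one). Each node
#' carries the rectangle-rule quadrature weight `domain_length / n_x`, so
#' weighted sums over the grid approximate integrals over the domain and the
#' discrete orthogonality of integer-frequency sines is exact.
#'
#' @param n_x number of grid nodes (at least 2).
#' @param domain_length length of the periodic domain; defaults to `2 * pi`.
#' @return An object of class `nf_grid` with fields `coords` (node
#'   coordinates), `weights` (quadrature weights), `topology`
#'   (`"periodic-1d"`), and `n_x`.
#' @examples
#' g <- make_grid_1d(100)
#' sum(g$weights)  # equals 2*pi
#' @export
make_grid_1d <- function(n_x, domain_length = 2 * pi) {
  if (!is.numeric(n_x) || length(n_x) != 1L || n_x < 2 || n_x != round(n_x))
    stop("`n_x` must be a single integer >= 2")
  if (!is.numeric(domain_length) || length(domain_length) != 1L ||
      domain_length <= 0)
    stop("`domain_length` must be a single positive number")
  n_x <- as.integer(n_x)
  dx <- domain_length / n_x
  structure(
    list(coords = (seq_len(n_x) - 1) * dx,
         weights = rep(dx, n_x),
         topology = "periodic-1d",
         n_x = n_x,
         domain_length = domain_length),
    class = "nf_grid")
}

#' Pixel grid on a two-dimensional image domain
#'
#' Builds the flat pixel lattice used by the two-dimensional experiments.
#' Pixels have unit area (weight 1 per node, no physical units) and are
#' enumerated row-major: pixel `(r, c)` (1-based) is node
#' `(r - 1) * ncol + c`.
#'
#' @param nrow,ncol image dimensions in pixels.
#' @return An `nf_grid` with `coords` an `n_x x 2` matrix of (row, col)
#'   indices, unit `weights`, topology `"pixel-2d"`, and `dims = c(nrow, ncol)`.
#' @export
make_grid_2d <- function(nrow = 20, ncol = nrow) {
  if (nrow < 1 || ncol < 1) stop("grid dimensions must be positive")
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  coords <- cbind(row = rep(seq_len(nrow), each = ncol),
                  col = rep(seq_len(ncol), times = nrow))
  structure(
    list(coords = coords,
         weights = rep(1, nrow * ncol),
         topology = "pixel-2d",
         n_x = nrow * ncol,
         dims = c(nrow, ncol)),
    class = "nf_grid")
}

#' @export
print.nf_grid <- function(x, ...) {
  cat("<nf_grid> ", x$topology, ", ", x$n_x, " nodes", sep = "")
  if (x$topology == "periodic-1d")
    cat(", domain length ", format(x$domain_length), sep = "")
  if (x$topology == "pixel-2d")
    cat(" (", x$dims[1], " x ", x$dims[2], ")", sep = "")
  cat("\n")
  invisible(x)
}

# internal: check two grids refer to the same discretization
same_grid <- function(a, b) {
  a$topology == b$topology && a$n_x == b$n_x &&
    isTRUE(all.equal(a$weights, b$weights))
}
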
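#' Render a grayscale digit pattern
#'
#' Deterministic, font-free rendering of the digits 1, 2, 3 as grayscale
#' bitmaps: each digit is a fixed set of polyline strokes in the unit
#' square, drawn with stroke width 1/8 of the image height and anti-aliased
#' over one pixel. The same label and resolution always yield the identical
#' array.
#'
#' @param label which digit, one of 1, 2, 3.
#' @param resolution image side length in pixels (square, at least 20).
#' @return An object of class `nf_digit`: list with `pixels`
#'   (resolution x resolution matrix in `[0, 1]`, row 1 = top), `label`,
#'   `resolution`.
#' @examples
#' d <- render_digit(2, 100)
#' range(d$pixels)
#' @export
render_digit <- function(label, resolution = 100) {
  if (!label %in% c(1, 2, 3)) stop("unsupported label: digits 1, 2, 3 only")
  if (resolution < 20) stop("resolution must be at least 20 x 20")
  strokes <- digit_strokes(label)
  res <- as.integer(resolution)
  # pixel centers in unit-square coordinates (x right, y down)
  cs <- (seq_len(res) - 0.5) / res
  px <- matrix(rep(cs, each = res), res, res)    # column index -> x
  py <- matrix(rep(cs, times = res), res, res)   # row index    -> y
  d <- matrix(Inf, res, res)
  for (s in strokes) {
    for (i in seq_len(nrow(s) - 1L)) {
      d <- pmin(d, dist_to_segment(px, py, s[i, 1L], s[i, 2L],
                                   s[i + 1L, 1L], s[i + 1L, 2L]))
    }
  }
  half_width <- 1 / 16            # stroke width 1/8 of the height
  aa <- 1 / res                   # one-pixel anti-aliasing ramp
  pixels <- matrix(pmin(1, pmax(0, (half_width + aa / 2 - d) / aa)),
                   res, res)
  structure(list(pixels = pixels, label = as.integer(label),
                 resolution = c(res, res)),
            class = "nf_digit")
}

# internal: fixed polyline stroke templates, unit square, y pointing down
digit_strokes <- function(label) {
  switch(as.character(label),
    "1" = list(rbind(c(0.35, 0.28), c(0.52, 0.14)),
               rbind(c(0.52, 0.14), c(0.52, 0.84)),
               rbind(c(0.32, 0.84), c(0.70, 0.84))),
    "2" = list(rbind(c(0.30, 0.30), c(0.34, 0.19), c(0.45, 0.13),
                     c(0.58, 0.14), c(0.67, 0.22), c(0.68, 0.34),
                     c(0.60, 0.48), c(0.44, 0.62), c(0.30, 0.76),
                     c(0.30, 0.84)),
               rbind(c(0.30, 0.84), c(0.70, 0.84))),
    "3" = list(rbind(c(0.32, 0.22), c(0.42, 0.14), c(0.56, 0.13),
                     c(0.66, 0.21), c(0.65, 0.33), c(0.55, 0.43),
                     c(0.45, 0.46)),
               rbind(c(0.45, 0.46), c(0.58, 0.50), c(0.67, 0.59),
                     c(0.67, 0.72), c(0.57, 0.83), c(0.42, 0.86),
                     c(0.31, 0.78))))
}

# internal: distance from points (px, py) to segment (x1,y1)-(x2,y2)
dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx +
                                              (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' @export
print.nf_digit <- function(x, ...) {
  cat("<nf_digit> \"", x$label, "\" at ", x$resolution[1L], " x ",
      x$resolution[2L], "\n", sep = "")
  invisible(x)
}

#' Downsample a pattern by block-mean pooling
#'
#' Reduces the resolution by averaging non-overlapping pixel blocks; the
#' source resolution must be an integer multiple of the target.
#'
#' @param pattern an `nf_digit` (or any list with a `pixels` matrix).
#' @param target integer length-2 target resolution (default `c(20, 20)`).
#' @return An `nf_digit` at the target resolution, values still in `[0, 1]`.
#' @export
downsample_pattern <- function(pattern, target = c(20, 20)) {
  src <- dim(pattern$pixels)
  target <- as.integer(rep_len(target, 2L))
  if (any(src %% target != 0))
    stop("source resolution ", src[1L], "x", src[2L],
         " is not an integer multiple of the target ",
         target[1L], "x", target[2L])
  f <- src %/% target
  p <- pattern$pixels
  # average over f[1] x f[2] blocks
  p <- matrix(colMeans(matrix(p, nrow = f[1L])), target[1L], src[2L])
  p <- t(matrix(colMeans(matrix(t(p), nrow = f[2L])), target[2L], target[1L]))
  structure(list(pixels = p, label = pattern$label %||% NA_integer_,
                 resolution = target),
            class = "nf_digit")
}

#' Flatten digit patterns into a 2D mode set
#'
#' Reshapes each 20 x 20 pattern into a length-400 vector (row-major: pixel
#' `(r, c)` maps to node `(r - 1) * 20 + c`) and stacks them as mode rows on
#' the pixel grid. By default each pattern is centered to zero mean first:
#' the shared background level otherwise makes the raw bitmaps strongly
#' collinear. The raw patterns are kept alongside for image export.
#'
#' @param patterns list of `nf_digit` objects at a common resolution.
#' @param centering subtract each pattern's mean before use (default TRUE).
#' @return An `nf_modes` on the matching [make_grid_2d()] grid, with the
#'   original patterns attached as attribute `"patterns"`.
#' @export
digits_to_modeset <- function(patterns, centering = TRUE) {
  dims <- lapply(patterns, function(p) dim(p$pixels))
  if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    stop("all patterns must share the same resolution")
  d <- dims[[1L]]
  vals <- t(vapply(patterns, function(p) {
    v <- as.vector(t(p$pixels))          # row-major flattening
    if (centering) v - mean(v) else v
  }, numeric(prod(d))))
  m <- modeset(vals, make_grid_2d(d[1L], d[2L]), provenance = "digits")
  attr(m, "patterns") <- patterns
  m
}

#' Select maximally selective probe pixels
#'
#' For each mode k, picks the pixel where that mode is strong while all
#' others are weak, maximizing the contrast ratio
#' `|v_k(i)| / max_{j != k} |v_j(i)|`. Activity recorded at such a pixel
#' tracks the emergence of pattern k and stays low while the other patterns
#' dominate. If no pixel has contrast ratio above 1 the argmax of `|v_k|`
#' is returned with a warning.
#'
#' @param modes an `nf_modes` (typically from [digits_to_modeset()]).
#' @return integer vector of node indices, one per mode, with the contrast
#'   ratios as attribute `"contrast"`.
#' @export
select_probe_points <- function(modes) {
  V <- abs(modes$values)
  n <- nrow(V)
  probes <- integer(n); contrast <- numeric(n)
  for (k in seq_len(n)) {
    others <- apply(V[-k, , drop = FALSE], 2L, max)
    ratio <- V[k, ] / pmax(others, .Machine$double.eps)
    i <- which.max(ratio)
    if (ratio[i] <= 1) {
      warning("no pixel with positive contrast for mode ", k,
              "; falling back to argmax |v_k|")
      i <- which.max(V[k, ])
    }
    probes[k] <- i; contrast[k] <- ratio[i]
  }
  structure(probes, contrast = contrast)
}
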
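#' Export a Lotka-Volterra trajectory as CSV
#'
#' Writes `time,xi_1..xi_n,alpha_1..alpha_n` with full double precision.
#'
#' @param traj an `nf_lv_traj`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_lv_csv <- function(traj, path) {
  n <- ncol(traj$xi)
  df <- data.frame(time = traj$times, traj$xi, traj$alpha)
  names(df) <- c("time", paste0("xi_", seq_len(n)),
                 paste0("alpha_", seq_len(n)))
  write_csv_full(df, path)
}

#' Export a field trajectory as long-format CSV
#'
#' Columns `time,node,value`, node indices 1-based.
#'
#' @param traj an `nf_field_traj`.
#' @param path output file path.
#' @param stride keep every `stride`-th time point (default 1, all).
#' @return the path, invisibly.
#' @export
write_field_csv <- function(traj, path, stride = 1L) {
  keep <- seq(1L, length(traj$times), by = stride)
  df <- data.frame(
    time = rep(traj$times[keep], each = ncol(traj$states)),
    node = rep(seq_len(ncol(traj$states)), times = length(keep)),
    value = as.vector(t(traj$states[keep, , drop = FALSE])))
  write_csv_full(df, path)
}

#' Export modes or adjoints as a CSV matrix
#'
#' One row per mode, one column per grid node.
#'
#' @param x an `nf_modes` or `nf_adjoints`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_modes_csv <- function(x, path) {
  df <- as.data.frame(x$values)
  names(df) <- paste0("node_", seq_len(ncol(df)))
  write_csv_full(cbind(mode = seq_len(nrow(df)), df), path)
}

#' Write a grayscale image as PGM
#'
#' Plain-text (P2) or binary (P5) portable graymap, 8-bit.
#'
#' @param pixels matrix in `[0, 1]`, row 1 = top image row.
#' @param path output file path.
#' @param type `"P2"` (ASCII, default) or `"P5"` (binary).
#' @return the path, invisibly.
#' @export
write_pgm <- function(pixels, path, type = c("P2", "P5")) {
  type <- match.arg(type)
  g <- matrix(round(pmin(1, pmax(0, pixels)) * 255),
              nrow(pixels), ncol(pixels))
  if (type == "P2") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
    utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(g), nrow(g)), con,
              eos = NULL)
    writeBin(as.raw(as.vector(t(g))), con)
  }
  invisible(path)
}

#' Read a plain (P2) PGM image
#'
#' @param path file written by [write_pgm()] or any plain PGM.
#' @return matrix of gray values rescaled to `[0, 1]`.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE,
               comment.char = "#")
  if (toks[1L] != "P2") stop("only plain (P2) PGM supported")
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  maxval <- as.numeric(toks[4L])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a grayscale image as PNG
#'
#' @param pixels matrix in `[0, 1]`, row 1 = top image row.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_png_gray <- function(pixels, path) {
  png::writePNG(matrix(pmin(1, pmax(0, pixels)),
                       nrow(pixels), ncol(pixels)), target = path)
  invisible(path)
}

#' Export an ensemble as per-probe CSV files plus a JSON summary
#'
#' One CSV per probe site (`<prefix>_probe<site>.csv` with columns
#' `time,trial_1..trial_m,grand_average`, trials = accepted noisy traces,
#' 1-based probe labels) and `<prefix>_summary.json` (accepted/rejected
#' counts, rejection reasons, config echo).
#'
#' @param ensemble an `nf_ensemble`.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, prefix) {
  acc <- which(ensemble$accepted)
  files <- character(0)
  for (p in seq_along(ensemble$probe_sites)) {
    tr <- vapply(acc, function(i) ensemble$noisy[[i]][, p],
                 numeric(length(ensemble$times)))
    df <- data.frame(time = ensemble$times, tr,
                     grand_average = ensemble$grand_average[, p])
    names(df) <- c("time", paste0("trial_", seq_along(acc)),
                   "grand_average")
    f <- sprintf("%s_probe%d.csv", prefix, ensemble$probe_sites[p])
    write_csv_full(df, f)
    files <- c(files, f)
  }
  sm <- list(n_trials = length(ensemble$accepted),
             accepted = sum(ensemble$accepted),
             rejected = sum(!ensemble$accepted),
             rejection_reasons = ensemble$reasons[!ensemble$accepted],
             probe_sites = ensemble$probe_sites,
             rejection_bound = ensemble$rejection_bound,
             config = unclass(ensemble$config))
  f <- paste0(prefix, "_summary.json")
  jsonlite::write_json(sm, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(files, f))
}

#' Export factored kernels as CSV blocks
#'
#' Writes modes, adjoints, `c1`, and `c2` as separate CSV files
#' (`<prefix>_modes.csv` etc.) at full double precision so that
#' [read_kernels_csv()] restores them bit-exactly.
#'
#' @param kernels an `nf_kernels` (the factored fields are written for
#'   either representation).
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_kernels_csv <- function(kernels, prefix) {
  paths <- c(modes = paste0(prefix, "_modes.csv"),
             adjoints = paste0(prefix, "_adjoints.csv"),
             c1 = paste0(prefix, "_c1.csv"),
             c2 = paste0(prefix, "_c2.csv"),
             weights = paste0(prefix, "_weights.csv"))
  write_csv_full(as.data.frame(kernels$modes$values), paths["modes"])
  write_csv_full(as.data.frame(kernels$adjoints$values), paths["adjoints"])
  write_csv_full(data.frame(c1 = kernels$c1), paths["c1"])
  write_csv_full(as.data.frame(kernels$c2), paths["c2"])
  write_csv_full(data.frame(w = kernels$modes$grid$weights),
                 paths["weights"])
  invisible(paths)
}

#' Restore factored kernels from CSV blocks
#'
#' Inverse of [write_kernels_csv()]. The grid topology is reconstructed as
#' generic (weights only), sufficient for [field_rhs()] and
#' [simulate_field()].
#'
#' @param prefix the path prefix used when writing.
#' @return an `nf_kernels` with representation `"factored"`.
#' @export
read_kernels_csv <- function(prefix) {
  rd <- function(suffix) as.matrix(utils::read.csv(paste0(prefix, suffix)))
  V <- unname(rd("_modes.csv"))
  A <- unname(rd("_adjoints.csv"))
  c1 <- as.numeric(rd("_c1.csv"))
  c2 <- unname(rd("_c2.csv"))
  w <- as.numeric(rd("_weights.csv"))
  grid <- structure(list(coords = seq_along(w), weights = w,
                         topology = "restored", n_x = length(w)),
                    class = "nf_grid")
  sigma <- c1 - 1
  rho <- -sweep(c2, 2L, sigma, "/")
  structure(list(representation = "factored",
                 modes = modeset(V, grid, provenance = "restored"),
                 adjoints = adjointset(A, grid, provenance = "restored"),
                 contour = as_contour(sigma, rho),
                 c1 = c1, c2 = c2),
            class = "nf_kernels")
}

# internal: CSV writer preserving full double precision
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
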
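#' Jaccard overlap between probe dominance and winner intervals
#'
#' Quantifies how well the activity recorded at the selective probe pixels
#' tracks the emergence intervals of their patterns. For each mode k the
#' probe trace is normalized by the mode's own value at its probe,
#' `a_k(t) = u(x_k, t) / v_k(x_k)`, and thresholded at
#' `dominance_threshold`; the resulting time mask is compared with the
#' winner-take-all dwell intervals of mode k (from [winner_sequence()]) by
#' the Jaccard index `|A intersect B| / |A union B|` over the trajectory's
#' time samples.
#'
#' @param traj an `nf_field_traj`.
#' @param modes the prescribed `nf_modes`.
#' @param probes integer node indices, one per mode (see
#'   [select_probe_points()]).
#' @param ws winner-sequence data frame on the same run (typically from the
#'   projected amplitudes).
#' @param dominance_threshold threshold on the normalized probe amplitude.
#' @return numeric vector of Jaccard indices in `[0, 1]`, one per mode.
#' @export
probe_dominance_jaccard <- function(traj, modes, probes, ws,
                                    dominance_threshold = 0.9) {
  n <- modes$n
  if (length(probes) != n) stop("need one probe per mode")
  vapply(seq_len(n), function(k) {
    vk <- modes$values[k, probes[k]]
    a <- traj$states[, probes[k]] / vk
    probe_mask <- a > dominance_threshold
    iv <- ws[ws$mode == k, , drop = FALSE]
    win_mask <- rep(FALSE, length(traj$times))
    for (i in seq_len(nrow(iv)))
      win_mask <- win_mask |
        (traj$times >= iv$t_on[i] & traj$times <= iv$t_off[i])
    u <- sum(probe_mask | win_mask)
    if (u == 0) return(0)
    sum(probe_mask & win_mask) / u
  }, numeric(1L))
}

#' Root-mean-square amplitude of a trace over a time window
#'
#' Convenience metric used to quantify the decay of the grand average.
#'
#' @param times time vector.
#' @param trace numeric vector or matrix (time x k).
#' @param window numeric `c(from, to)`.
#' @return scalar RMS over all samples in the window.
#' @export
window_rms <- function(times, trace, window) {
  sel <- times >= window[1L] & times <= window[2L]
  if (!any(sel)) stop("window contains no samples")
  trace <- as.matrix(trace)
  sqrt(mean(trace[sel, , drop = FALSE]^2))
}
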
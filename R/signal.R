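## Fluorescence signal processing: dF/F, baseline-noise estimation,
## significant-transient masking and lap x bin spatial activity maps.

#' Convert raw fluorescence to dF/F
#'
#' The baseline F0 is the 50th percentile (median) of a centred 25-s moving
#' window, truncated at the trace edges. dF/F = (F - F0) / F0.
#'
#' @param raw raw fluorescence trace (one cell), numeric vector.
#' @param frame_rate acquisition rate in Hz.
#' @param window_s baseline window length in seconds.
#' @return object of class `dff_trace`: list with `values` (dF/F per frame),
#'   `f0` (baseline per frame) and `frame_rate`.
#' @export
compute_dff <- function(raw, frame_rate = 30, window_s = 25) {
  stopifnot(length(raw) >= 1, frame_rate > 0)
  if (any(!is.finite(raw))) stop("raw fluorescence contains non-finite values")
  n <- length(raw)
  w <- round(window_s * frame_rate)
  h <- w %/% 2
  k <- 2L * h + 1L                      # odd window for the interior
  if (n >= k && k >= 3) {
    f0 <- as.numeric(stats::runmed(raw, k, endrule = "keep"))
    ## truncated centred windows at the edges
    edge <- seq_len(min(h, n))
    for (i in edge) f0[i] <- stats::median(raw[1:min(n, i + h)])
    for (i in (n - rev(edge) + 1)) f0[i] <- stats::median(raw[max(1, i - h):n])
  } else {
    f0 <- vapply(seq_len(n), function(i)
      stats::median(raw[max(1, i - h):min(n, i + h)]), numeric(1))
  }
  if (any(f0 <= 0)) stop("nonpositive baseline F0; cannot form dF/F")
  structure(list(values = (raw - f0) / f0, f0 = f0, frame_rate = frame_rate),
            class = "dff_trace")
}

#' Estimate baseline noise of a dF/F trace
#'
#' The noise s.d. is computed from the negative-going deviations around the
#' mode of the dF/F histogram, so sparse positive transients do not inflate
#' the estimate. The mode is located by a coarse-to-fine histogram search
#' with an initial bin width of one tenth of a robust scale estimate.
#'
#' @param dff a `dff_trace` or numeric vector of dF/F values.
#' @return estimated noise s.d. in dF/F units (0, with a warning, for a
#'   degenerate constant trace).
#' @export
estimate_baseline_noise <- function(dff) {
  x <- if (inherits(dff, "dff_trace")) dff$values else as.numeric(dff)
  stopifnot(length(x) >= 100)
  rng <- diff(range(x))
  scale0 <- stats::mad(x)
  ## a near-zero MAD (mostly-silent trace) is not a usable noise scale
  if (!is.finite(scale0) || scale0 < 1e-6 * rng) scale0 <- stats::sd(x)
  if (!is.finite(scale0) || scale0 == 0) {
    warning("degenerate (constant) trace; returning noise sd = 0")
    return(0)
  }
  mode_est <- .hist_mode(x, scale0 / 10)
  ## refine around the coarse mode with a 5x finer grid
  near <- x[abs(x - mode_est) <= 2 * scale0]
  if (length(near) > 50) mode_est <- .hist_mode(near, scale0 / 50)
  below <- x[x <= mode_est]
  sqrt(mean((below - mode_est)^2))
}

.hist_mode <- function(x, bw, max_bins = 5000) {
  bw <- max(bw, diff(range(x)) / max_bins)
  br <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Mask significant calcium transients
#'
#' A transient is a contiguous epoch in which dF/F stays above
#' `extend_sd` noise s.d.; the epoch is retained as functional activity only
#' if its peak exceeds `threshold_sd` noise s.d. All other frames are zeroed
#' downstream. Raising `threshold_sd` can only shrink the mask.
#'
#' @param dff a `dff_trace` or numeric vector of dF/F values.
#' @param noise_sd baseline noise s.d.; estimated from the trace if `NULL`.
#' @param threshold_sd peak threshold in noise s.d. units (3 by default).
#' @param extend_sd epoch-extension level in noise s.d. units.
#' @return logical vector, `TRUE` for frames inside significant transients.
#' @export
detect_significant_transients <- function(dff, noise_sd = NULL,
                                          threshold_sd = 3, extend_sd = 1) {
  x <- if (inherits(dff, "dff_trace")) dff$values else as.numeric(dff)
  if (is.null(noise_sd)) noise_sd <- estimate_baseline_noise(x)
  mask <- rep(FALSE, length(x))
  if (noise_sd == 0) return(x > 0)
  runs <- true_runs(x > extend_sd * noise_sd)
  if (nrow(runs) == 0) return(mask)
  for (i in seq_len(nrow(runs))) {
    idx <- runs[i, 1]:runs[i, 2]
    if (max(x[idx]) > threshold_sd * noise_sd) mask[idx] <- TRUE
  }
  mask
}

#' Build a lap x bin spatial activity map
#'
#' Divides the belt into `n_bins` equal bins and, for every lap and bin,
#' averages dF/F over the frames in which the animal ran faster than
#' `velocity_threshold`. Bins with no qualifying frame are `NA` (missing,
#' not silent). Input traces should already be transient-masked if only
#' significant activity is to be counted.
#'
#' @param traces matrix of dF/F, cells x frames (a vector is treated as one
#'   cell).
#' @param position per-frame belt position in cm, `[0, track_length)`.
#' @param velocity per-frame running speed in cm/s.
#' @param lap per-frame lap index (1-based).
#' @param lap_condition character vector, reward condition ("RL1"/"RL2") per
#'   lap.
#' @param n_bins,track_length spatial discretization (50 bins x 3.6 cm).
#' @param velocity_threshold minimum speed in cm/s for a frame to count.
#' @return object of class `spatial_map`: list with `maps` (3-d array cell x
#'   lap x bin), `lap_condition`, `bin_width`, `occupancy` (lap x bin
#'   qualifying-frame counts).
#' @export
compute_spatial_map <- function(traces, position, velocity, lap,
                                lap_condition = NULL, n_bins = 50,
                                track_length = 180, velocity_threshold = 2) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  n_frames <- ncol(traces)
  if (length(position) != n_frames || length(velocity) != n_frames ||
      length(lap) != n_frames)
    stop("misaligned streams: traces, position, velocity and lap must cover the same frames")
  n_laps <- max(lap)
  keep <- velocity > velocity_threshold
  bin <- position_to_bin(position, n_bins, track_length)
  grp <- (bin - 1L) * n_laps + lap      # column-major (lap, bin) linear index
  occ <- tabulate(grp[keep], nbins = n_laps * n_bins)
  maps <- array(NA_real_, dim = c(nrow(traces), n_laps, n_bins))
  if (any(keep)) {
    sums <- rowsum(t(traces[, keep, drop = FALSE]), group = grp[keep])
    gid <- as.integer(rownames(sums))
    cnt <- occ[gid]
    means <- sums / cnt
    for (ci in seq_len(nrow(traces))) {
      m <- matrix(NA_real_, n_laps, n_bins)
      m[gid] <- means[, ci]
      maps[ci, , ] <- m
    }
  }
  structure(list(maps = maps,
                 lap_condition = lap_condition,
                 bin_width = track_length / n_bins,
                 track_length = track_length,
                 occupancy = matrix(occ, n_laps, n_bins)),
            class = "spatial_map")
}
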
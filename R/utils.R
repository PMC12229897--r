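#' Circular distance on the belt
#'
#' Unsigned distance between two track positions on a circular belt.
#'
#' @param a,b positions in cm, in `[0, track_length)`.
#' @param track_length belt length in cm.
#' @return unsigned distance in cm, in `[0, track_length/2]`.
#' @export
circ_dist <- function(a, b, track_length = 180) {
  d <- abs(a - b) %% track_length
  pmin(d, track_length - d)
}

#' Signed circular difference `b - a`
#'
#' Signed shift from `a` to `b` on the belt, wrapped into
#' `(-track_length/2, track_length/2]`. Negative values are backward
#' relative to the running direction.
#'
#' @inheritParams circ_dist
#' @return signed shift in cm.
#' @export
circ_diff <- function(a, b, track_length = 180) {
  d <- (b - a) %% track_length
  ifelse(d > track_length / 2, d - track_length, d)
}

#' Bin centres of the spatial discretization
#'
#' @param n_bins number of spatial bins.
#' @param track_length belt length in cm.
#' @return numeric vector of bin-centre positions in cm.
#' @export
bin_centers <- function(n_bins = 50, track_length = 180) {
  bw <- track_length / n_bins
  (seq_len(n_bins) - 0.5) * bw
}

## position (cm) -> 1-based bin index
position_to_bin <- function(x, n_bins = 50, track_length = 180) {
  b <- floor((x %% track_length) / (track_length / n_bins)) + 1L
  pmin(b, n_bins)
}

## circular index shift of a vector (positive k moves contents to higher bins)
rotate_vec <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

## runs of TRUE in a logical vector -> matrix with columns start, end
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

## activity-weighted circular mean position (centre of mass) of a lap profile.
## Uses the vector mean on the circle so fields straddling the belt seam are
## handled correctly. `x` are positions, `w` nonnegative weights.
circ_com <- function(x, w, track_length = 180) {
  keep <- !is.na(w) & w > 0
  if (!any(keep)) return(NA_real_)
  th <- 2 * pi * x[keep] / track_length
  m <- atan2(sum(w[keep] * sin(th)), sum(w[keep] * cos(th)))
  (m %% (2 * pi)) * track_length / (2 * pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
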
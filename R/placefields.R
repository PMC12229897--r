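## Place-field detection: spatial information, shuffle test, and the four
## per-epoch criteria (information, peak gating, 3-of-5 onset, reliability).

#' Skaggs spatial information of an epoch map
#'
#' Information (bits per unit mean activity) of the bin-averaged activity
#' relative to occupancy: `sum_i p_i (l_i / L) log2(l_i / L)` with `l_i` the
#' mean activity in bin i, `p_i` the occupancy fraction and `L = sum p_i l_i`.
#'
#' @param epoch_map lap x bin activity matrix (NA = unvisited).
#' @param occupancy occupancy weights per bin; defaults to the per-bin count
#'   of non-missing lap entries.
#' @return nonnegative scalar, or `NA` (with a warning) if the epoch has no
#'   activity data.
#' @export
spatial_information <- function(epoch_map, occupancy = NULL) {
  epoch_map <- rbind(epoch_map)          # tolerate a single-lap vector
  lam <- colMeans(epoch_map, na.rm = TRUE)
  if (all(is.nan(lam))) {
    warning("epoch map has no visited bins; spatial information undefined")
    return(NA_real_)
  }
  if (is.null(occupancy)) occupancy <- colSums(!is.na(epoch_map))
  keep <- !is.nan(lam) & occupancy > 0
  p <- occupancy[keep] / sum(occupancy[keep])
  lam <- pmax(lam[keep], 0)
  L <- sum(p * lam)
  if (L <= 0) return(0)
  r <- lam / L
  pos <- r > 0
  sum(p[pos] * r[pos] * log2(r[pos]))
}

#' Shuffle test for spatial information
#'
#' Builds a null distribution by circularly rotating each lap's binned
#' activity by an independent random offset and recomputing the information
#' of the rotated epoch. The observed epoch passes if its information
#' exceeds the 95th percentile of the null.
#'
#' @inheritParams spatial_information
#' @param n_shuffles number of shuffles (>= 100).
#' @param percentile null percentile defining the pass threshold.
#' @return list with `observed`, `threshold`, `pass` and `p_value`.
#' @export
shuffle_test <- function(epoch_map, n_shuffles = 1000, percentile = 0.95,
                         occupancy = NULL) {
  stopifnot(n_shuffles >= 100)
  epoch_map <- rbind(epoch_map)
  n_bins <- ncol(epoch_map)
  obs <- spatial_information(epoch_map, occupancy)
  if (is.na(obs))
    return(list(observed = NA_real_, threshold = NA_real_, pass = FALSE,
                p_value = NA_real_))
  filled <- epoch_map
  filled[is.na(filled)] <- 0             # rotation needs complete rows
  occ <- occupancy %||% colSums(!is.na(epoch_map))
  ## accumulate the shuffled mean maps: shuffle x bin
  acc <- matrix(0, n_shuffles, n_bins)
  cols <- matrix(seq_len(n_bins), n_shuffles, n_bins, byrow = TRUE)
  for (l in seq_len(nrow(epoch_map))) {
    off <- sample.int(n_bins, n_shuffles, replace = TRUE) - 1L
    idx <- ((cols - 1L - off) %% n_bins) + 1L
    acc <- acc + matrix(filled[l, idx], n_shuffles, n_bins)
  }
  acc <- acc / nrow(epoch_map)
  p <- occ / sum(occ)
  L <- as.numeric(acc %*% p)
  r <- acc / ifelse(L > 0, L, 1)
  term <- r * log2(pmax(r, 1e-300)) * (r > 0)
  null_si <- as.numeric(term %*% p)
  null_si[L <= 0] <- 0
  thr <- stats::quantile(null_si, percentile, names = FALSE)
  list(observed = obs, threshold = thr, pass = obs > thr,
       p_value = mean(null_si >= obs))
}

## laps whose peak lies within `gate_cm` (circular) of the epoch-average peak
## and that contain any activity. Returns a logical per row of `m`.
.active_laps <- function(m, gate_cm, bin_width, track_length) {
  avg <- colMeans(m, na.rm = TRUE)
  avg[is.nan(avg)] <- -Inf
  peak_bin <- which.max(avg)             # ties -> lowest bin index
  ctr <- (seq_len(ncol(m)) - 0.5) * bin_width
  vapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    if (all(is.na(row)) || max(row, na.rm = TRUE) <= 0) return(FALSE)
    pb <- which.max(ifelse(is.na(row), -Inf, row))
    circ_dist(ctr[pb], ctr[peak_bin], track_length) <= gate_cm
  }, logical(1))
}

## earliest 5-lap sliding window with >= 3 active laps; onset = first active
## lap inside it. Returns the onset index within the epoch, or NA.
.onset_lap <- function(active, window = 5, need = 3) {
  n <- length(active)
  if (n < need) return(NA_integer_)
  for (s in seq_len(max(1, n - window + 1))) {
    w <- active[s:min(n, s + window - 1)]
    if (sum(w) >= need) return(s - 1L + which(w)[1])
  }
  NA_integer_
}

#' Detect a place field for one cell, day and reward condition
#'
#' Applies four criteria per behavioral epoch (block of consecutive laps of
#' one condition): (1) the epoch's spatial information exceeds the shuffle
#' null's 95th percentile; (2) laps count as place-field active only if
#' their peak dF/F lies within `gate_cm` (54 cm, circular) of the epoch-
#' average peak; (3) an onset lap exists as the first instance where three
#' of five laps show field activity; (4) the active-lap reliability after
#' the onset lap is at least `reliability_min`. A field is reported if at
#' least one epoch passes all four. The field location is the peak of the
#' lap-averaged activity over all laps of the passing epochs, reported at
#' the bin centre.
#'
#' @param cell_map lap x bin activity matrix for the laps of one condition
#'   (in session order).
#' @param epochs list of integer vectors: row indices of `cell_map` per
#'   behavioral epoch.
#' @param lap_numbers session lap number of each row of `cell_map` (used to
#'   report the onset lap on the session lap axis); defaults to row index.
#' @param n_shuffles shuffles for criterion 1.
#' @param gate_cm criterion-2 peak gate in cm.
#' @param reliability_min criterion-4 threshold.
#' @param track_length belt length in cm.
#' @return one-row data.frame (pf_location_cm, onset_lap, reliability,
#'   spatial_info, n_epochs_passed) or `NULL` if no epoch passes.
#' @export
detect_place_field <- function(cell_map, epochs, lap_numbers = NULL,
                               n_shuffles = 1000, gate_cm = 54,
                               reliability_min = 0.40, track_length = 180) {
  if (is.null(lap_numbers)) lap_numbers <- seq_len(nrow(cell_map))
  bw <- track_length / ncol(cell_map)
  passed <- list()
  for (ep in epochs) {
    m <- cell_map[ep, , drop = FALSE]
    if (all(is.na(m)) || max(m, na.rm = TRUE) <= 0) next
    st <- shuffle_test(m, n_shuffles)
    if (!isTRUE(st$pass)) next
    active <- .active_laps(m, gate_cm, bw, track_length)
    on <- .onset_lap(active)
    if (is.na(on)) next
    after <- active[seq_along(active) > on]
    rel <- if (length(after)) mean(after) else 1
    if (rel < reliability_min) next
    passed[[length(passed) + 1]] <-
      list(ep = ep, onset = lap_numbers[ep][on], rel = rel, si = st$observed)
  }
  if (!length(passed)) return(NULL)
  all_laps <- unlist(lapply(passed, `[[`, "ep"))
  avg <- colMeans(cell_map[all_laps, , drop = FALSE], na.rm = TRUE)
  avg[is.nan(avg)] <- -Inf
  pb <- which.max(avg)
  data.frame(pf_location_cm = (pb - 0.5) * bw,
             onset_lap = min(vapply(passed, `[[`, numeric(1), "onset")),
             reliability = max(vapply(passed, `[[`, numeric(1), "rel")),
             spatial_info = max(vapply(passed, `[[`, numeric(1), "si")),
             n_epochs_passed = length(passed))
}

## condition blocks (epochs) from a per-lap condition vector
condition_epochs <- function(lap_condition) {
  r <- rle(as.character(lap_condition))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  split_list <- Map(function(s, e) s:e, starts, ends)
  names(split_list) <- r$values
  split_list
}

#' Detect place fields for every cell of a session
#'
#' Runs [detect_place_field()] per cell and reward condition of a spatial
#' map, using the session's 12-18-lap condition blocks as behavioral epochs.
#'
#' @param sp a `spatial_map` (see [compute_spatial_map()]) with
#'   `lap_condition` set.
#' @param mouse,day identifiers copied into the output.
#' @param ... passed to [detect_place_field()].
#' @return data.frame with one row per detected (cell, condition) field:
#'   mouse, day, condition, cell, pf_location_cm, onset_lap, reliability,
#'   spatial_info, n_epochs_passed.
#' @export
detect_place_fields <- function(sp, mouse = 1, day = 1, ...) {
  stopifnot(inherits(sp, "spatial_map"), !is.null(sp$lap_condition))
  eps <- condition_epochs(sp$lap_condition)
  out <- list()
  for (cond in unique(names(eps))) {
    cond_eps <- eps[names(eps) == cond]
    cond_laps <- sort(unlist(cond_eps))
    ## re-index epochs into the condition-subset map
    remap <- match(unlist(cond_eps), cond_laps)
    eps_local <- split(remap, rep(seq_along(cond_eps),
                                  lengths(cond_eps)))
    for (ci in seq_len(dim(sp$maps)[1])) {
      m <- sp$maps[ci, cond_laps, , drop = TRUE]
      if (all(is.na(m)) || max(m, na.rm = TRUE) <= 0) next
      rec <- detect_place_field(m, eps_local, lap_numbers = cond_laps,
                                track_length = sp$track_length, ...)
      if (!is.null(rec))
        out[[length(out) + 1]] <- cbind(
          data.frame(mouse = mouse, day = day, condition = cond, cell = ci),
          rec)
    }
  }
  if (!length(out))
    return(data.frame(mouse = integer(), day = integer(),
                      condition = character(), cell = integer(),
                      pf_location_cm = numeric(), onset_lap = numeric(),
                      reliability = numeric(), spatial_info = numeric(),
                      n_epochs_passed = integer()))
  do.call(rbind, out)
}
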
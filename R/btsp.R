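## BTSP induction-event detection in lap x bin activity, plateau-potential
## proxies in imaging, and plateau detection in membrane-potential traces.

## per-lap calcium events of a cell: one event per lap with activity, with
## its peak amplitude and peak location (bin centre, cm)
.lap_events <- function(m, track_length = 180) {
  bw <- track_length / ncol(m)
  amps <- apply(m, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  peaks <- apply(m, 1, function(r) {
    if (all(is.na(r)) || max(r, na.rm = TRUE) <= 0) return(NA_real_)
    (which.max(ifelse(is.na(r), -Inf, r)) - 0.5) * bw
  })
  data.frame(lap = seq_len(nrow(m)), amplitude = amps, peak_cm = peaks)
}

#' Detect putative BTSP induction events
#'
#' Scans a cell's lap x bin activity (one session, one reward condition)
#' for calcium events satisfying the four induction criteria:
#' (1) event amplitude in the top 20th percentile of all the cell's events
#' in the session and at least `min_amplitude` dF/F; (2) subsequent laps
#' count as field-active only if their peak lies within `gate_cm`
#' (circular) of the event peak; (3) at least 3 of the 5 laps after the
#' event lap are field-active; (4) the mean centre of mass of the
#' post-event active laps is shifted backward (negative) relative to the
#' event peak.
#'
#' @param m lap x bin activity matrix (transient-masked dF/F).
#' @param lap_velocity mean running speed (cm/s) per lap; recorded as the
#'   induction velocity of the event lap.
#' @param min_amplitude criterion-1 amplitude floor in dF/F.
#' @param amp_percentile criterion-1 percentile (0.8 = top 20th).
#' @param gate_cm criterion-2 gate in cm.
#' @param track_length belt length in cm.
#' @return data.frame of events: lap, amplitude, peak_cm, com_shift_cm,
#'   n_active_post, induction_velocity, pf_width_cm (width of the mean
#'   post-event field, cm), is_first. Empty if none.
#' @export
detect_btsp_events <- function(m, lap_velocity = NULL, min_amplitude = 1,
                               amp_percentile = 0.8, gate_cm = 45,
                               track_length = 180) {
  stopifnot(nrow(m) >= 6)
  ev <- .lap_events(m, track_length)
  has <- ev$amplitude > 0
  out <- list()
  if (any(has)) {
    thr <- stats::quantile(ev$amplitude[has], amp_percentile, names = FALSE)
    bw <- track_length / ncol(m)
    ctr <- bin_centers(ncol(m), track_length)
    for (i in which(has)) {
      if (ev$amplitude[i] < max(thr, min_amplitude)) next
      post <- i + 1:5
      post <- post[post <= nrow(m)]
      if (!length(post)) next
      act <- !is.na(ev$peak_cm[post]) &
        circ_dist(ev$peak_cm[post], ev$peak_cm[i], track_length) <= gate_cm
      if (sum(act) < 3) next
      post_act <- post[act]
      lap_com <- function(l) {
        row <- m[l, ]
        w <- ifelse(is.na(row), 0, pmax(row, 0))
        w[circ_dist(ctr, ev$peak_cm[i], track_length) > gate_cm] <- 0
        circ_com(ctr, w, track_length)
      }
      coms <- vapply(post_act, lap_com, numeric(1))
      ## reference = the event lap's own centre of mass (same estimator as
      ## the post laps, so bin quantization cancels)
      ref <- lap_com(i)
      shift <- mean(circ_diff(ref, coms, track_length))
      if (!is.finite(shift) || shift >= 0) next
      mean_field <- colMeans(m[post_act, , drop = FALSE], na.rm = TRUE)
      mean_field[is.nan(mean_field)] <- 0
      out[[length(out) + 1]] <- data.frame(
        lap = i, amplitude = ev$amplitude[i], peak_cm = ev$peak_cm[i],
        com_shift_cm = shift, n_active_post = sum(act),
        induction_velocity = if (is.null(lap_velocity)) NA_real_
                             else lap_velocity[i],
        pf_width_cm = .field_width(mean_field, bw))
    }
  }
  if (!length(out))
    return(data.frame(lap = integer(), amplitude = numeric(),
                      peak_cm = numeric(), com_shift_cm = numeric(),
                      n_active_post = integer(),
                      induction_velocity = numeric(),
                      pf_width_cm = numeric(), is_first = logical()))
  res <- do.call(rbind, out)
  res$is_first <- seq_len(nrow(res)) == 1
  res
}

## full width at half maximum of a circular mean-field profile, in cm, with
## the half-maximum crossings located by linear interpolation between bin
## centres (avoids 1-bin quantization of the width)
.field_width <- function(profile, bw) {
  n <- length(profile)
  pk <- max(profile)
  if (pk <= 0) return(NA_real_)
  if (all(profile >= pk / 2)) return(n * bw)
  half <- pk / 2
  ipk <- which.max(profile)
  ## rotate so the peak sits mid-vector; walk out to the crossings
  rot <- rotate_vec(profile, n %/% 2 - ipk + 1)
  ctr <- n %/% 2 + 1
  right <- ctr
  while (right < n && rot[right + 1] >= half) right <- right + 1
  left <- ctr
  while (left > 1 && rot[left - 1] >= half) left <- left - 1
  frac_r <- if (right < n && rot[right] > rot[right + 1])
    (rot[right] - half) / (rot[right] - rot[right + 1]) else 0
  frac_l <- if (left > 1 && rot[left] > rot[left - 1])
    (rot[left] - half) / (rot[left] - rot[left - 1]) else 0
  (right - left + frac_r + frac_l) * bw
}

#' Plateau-potential threshold and rate from imaging
#'
#' The calcium proxy threshold for a plateau potential is the minimum
#' amplitude of the BTSP events detected for that cell, session and
#' context; every calcium event at or above it counts as a putative
#' plateau.
#'
#' @param events BTSP events from [detect_btsp_events()].
#' @param event_amplitudes amplitudes of all the cell's calcium events in
#'   the session (one per active lap).
#' @param n_laps lap count of the session.
#' @return list with `threshold`, `n_plateaus`, `rate` (plateaus per lap);
#'   all `NA` (flagged) when no BTSP event was detected.
#' @export
plateau_threshold_and_rate <- function(events, event_amplitudes, n_laps) {
  if (is.null(events) || nrow(events) == 0)
    return(list(threshold = NA_real_, n_plateaus = NA_integer_,
                rate = NA_real_, flagged = TRUE))
  thr <- min(events$amplitude)
  n <- sum(event_amplitudes >= thr)
  list(threshold = thr, n_plateaus = n, rate = n / n_laps, flagged = FALSE)
}

#' Activity statistics before versus after the first BTSP event
#'
#' For the first event of a session (per cell and context), the mean lap
#' event amplitude and field reliability are computed separately over the
#' laps before and after the event lap. Silent laps contribute amplitude 0;
#' reliability is the fraction of laps with a peak within `gate_cm` of the
#' event location.
#'
#' @inheritParams detect_btsp_events
#' @param events output of [detect_btsp_events()] for the same map.
#' @return data.frame (one row per first event): pre_amplitude,
#'   post_amplitude, pre_reliability, post_reliability, flagged (TRUE when
#'   the event is on the first lap so the pre set is empty).
#' @export
pre_post_event_stats <- function(m, events, gate_cm = 45, track_length = 180) {
  firsts <- events[events$is_first, , drop = FALSE]
  if (nrow(firsts) == 0) return(firsts)
  ev <- .lap_events(m, track_length)
  out <- lapply(seq_len(nrow(firsts)), function(k) {
    i <- firsts$lap[k]
    pre <- seq_len(nrow(m)) < i
    post <- seq_len(nrow(m)) > i
    qual <- !is.na(ev$peak_cm) &
      circ_dist(ev$peak_cm, firsts$peak_cm[k], track_length) <= gate_cm
    data.frame(lap = i,
               pre_amplitude = if (any(pre)) mean(ev$amplitude[pre]) else NA_real_,
               post_amplitude = if (any(post)) mean(ev$amplitude[post]) else NA_real_,
               pre_reliability = if (any(pre)) mean(qual[pre]) else NA_real_,
               post_reliability = if (any(post)) mean(qual[post]) else NA_real_,
               flagged = !any(pre))
  })
  do.call(rbind, out)
}

#' Field width versus induction velocity regression
#'
#' Ordinary least squares of the induced field width on the running speed
#' in the induction lap.
#'
#' @param events data.frame with columns `pf_width_cm` and
#'   `induction_velocity` (pooled BTSP events).
#' @return list with `slope` (cm per cm/s), `intercept` (cm), `p_value`,
#'   `r_squared`, `n`.
#' @export
width_velocity_regression <- function(events) {
  ok <- stats::complete.cases(events[, c("pf_width_cm", "induction_velocity")])
  stopifnot(sum(ok) >= 10)
  if (stats::sd(events$induction_velocity[ok]) == 0)
    stop("degenerate induction velocities; regression undefined")
  fit <- stats::lm(pf_width_cm ~ induction_velocity, data = events[ok, ])
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = s$coefficients[2, 4], r_squared = s$r.squared, n = sum(ok))
}

#' Detect plateau potentials in a membrane-potential trace
#'
#' Action potentials are removed by deleting samples from `pre_ms` before
#' to `post_ms` after every upward crossing of the dVm/dt spike threshold
#' (25 V/s) and linearly interpolating the gaps; when spikes are present
#' the trace is baseline-corrected by the difference between the 5th
#' percentile of the spike-onset voltages and -50 mV. Plateaus are epochs
#' in which the despiked trace exceeds `vm_threshold`; crossings separated
#' by less than `merge_ms` belong to one plateau (consecutive theta
#' cycles), and a plateau is long-lasting if its total duration exceeds
#' `long_ms`.
#'
#' @param vm membrane potential in mV.
#' @param sampling_rate in Hz (>= 10 kHz).
#' @param vm_threshold plateau threshold in mV.
#' @param dvdt_threshold spike threshold in V/s.
#' @param pre_ms,post_ms spike-removal window in ms.
#' @param merge_ms merge gap in ms.
#' @param long_ms long-lasting duration bound in ms.
#' @param baseline_correct apply the spike-threshold baseline correction
#'   when spikes are detected.
#' @return data.frame per plateau: onset_s, duration_ms, merged_from,
#'   long_lasting.
#' @export
detect_vm_plateaus <- function(vm, sampling_rate, vm_threshold = -35,
                               dvdt_threshold = 25, pre_ms = 0.26,
                               post_ms = 3, merge_ms = 150, long_ms = 150,
                               baseline_correct = TRUE) {
  stopifnot(sampling_rate >= 10000)
  n <- length(vm)
  dvdt <- c(0, diff(vm)) * sampling_rate / 1000   # V/s (vm in mV)
  spk <- which(dvdt >= dvdt_threshold & c(0, dvdt[-n]) < dvdt_threshold)
  keep <- rep(TRUE, n)
  for (s in spk) {
    a <- max(1, s - round(pre_ms * sampling_rate / 1000))
    b <- min(n, s + round(post_ms * sampling_rate / 1000))
    keep[a:b] <- FALSE
  }
  v <- vm
  if (!all(keep)) {
    v[!keep] <- NA
    v <- stats::approx(which(keep), v[keep], xout = seq_len(n), rule = 2)$y
    if (baseline_correct && length(spk)) {
      thr_vm <- stats::quantile(vm[pmax(spk - 1, 1)], 0.05, names = FALSE)
      v <- v - (thr_vm - (-50))
    }
  }
  runs <- true_runs(v > vm_threshold)
  if (nrow(runs) == 0)
    return(data.frame(onset_s = numeric(), duration_ms = numeric(),
                      merged_from = integer(), long_lasting = logical()))
  df <- data.frame(start = runs[, "start"], end = runs[, "end"])
  merged <- merge_plateau_runs(df, sampling_rate, merge_ms)
  data.frame(onset_s = (merged$start - 1) / sampling_rate,
             duration_ms = merged$dur_ms,
             merged_from = merged$n,
             long_lasting = merged$dur_ms > long_ms)
}

## merge threshold-crossing runs whose gaps are < merge_ms; duration is the
## summed above-threshold time of the merged group. Idempotent.
merge_plateau_runs <- function(runs, sampling_rate, merge_ms = 150) {
  gap_max <- merge_ms * sampling_rate / 1000
  out <- list()
  cur <- c(runs$start[1], runs$end[1])
  dur <- runs$end[1] - runs$start[1] + 1
  cnt <- 1L
  flush <- function() data.frame(start = cur[1], end = cur[2],
                                 dur_ms = dur / sampling_rate * 1000, n = cnt)
  res <- NULL
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - cur[2] - 1 < gap_max) {
      cur[2] <- runs$end[i]
      dur <- dur + runs$end[i] - runs$start[i] + 1
      cnt <- cnt + 1L
    } else {
      res <- rbind(res, flush())
      cur <- c(runs$start[i], runs$end[i])
      dur <- runs$end[i] - runs$start[i] + 1
      cnt <- 1L
    }
  }
  rbind(res, flush())
}
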
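## Synthetic multi-day experiment generator. Emulates the study design --
## cued linear treadmill, two alternating reward conditions in 12-18-lap
## blocks, transient/sustained place-cell subpopulations with BTSP-like
## induction (large first event, backward centre-of-mass drift, width
## proportional to induction speed) -- with known ground truth, so every
## analysis stage is testable without recorded data.

#' Synthetic-experiment configuration
#'
#' Defaults reproduce the study conditions: 2,511 cells imaged at 30 Hz on
#' a 180-cm belt over 7 daily sessions of ~126 laps grouped in 12-18-lap
#' reward-condition blocks, an induced-field width of
#' `0.80 * speed + 18.95` cm, and a plateau-amplitude event rate of 0.06
#' per lap. Tests and examples scale `n_cells`/`laps_per_session` down.
#'
#' @param n_cells,n_mice,n_days population and session layout.
#' @param track_length,n_bins,frame_rate belt and acquisition geometry.
#' @param laps_per_session laps per daily session.
#' @param block_length_range lap-count interval of the reward-condition
#'   blocks.
#' @param reward_cm named vector of reward locations per condition.
#' @param cue_cm light-cue location.
#' @param frac_sustained,frac_transient per-condition fractions of cells
#'   assigned to the sustained / transient classes.
#' @param p_survival per-day survival probability of a sustained field.
#' @param p_transient_two_days probability a transient cell is active on a
#'   second (consecutive) day.
#' @param day_jitter_sd s.d. (cm) of the day-to-day field-centre jitter.
#' @param backward_shift_cm mean backward day-to-day drift of sustained
#'   fields.
#' @param pf_amplitude,btsp_amplitude dF/F of ordinary field events and of
#'   plateau-like induction events.
#' @param reliability post-onset active-lap probability.
#' @param btsp_width_slope,btsp_width_intercept induced-width regression
#'   (cm per cm/s; cm).
#' @param com_drift_cm,com_drift_decay initial backward COM offset after
#'   induction (cm) and its per-lap geometric decay.
#' @param plateau_rate plateau-amplitude events per lap.
#' @param v_run,v_slow running speed and the dip near reward (cm/s).
#' @param speed_jitter fractional lap-to-lap running-speed variability
#'   (uniform in `1 +/- speed_jitter`).
#' @param pf_amplitude_cv lognormal sigma of ordinary field-event
#'   amplitudes (0 = constant).
#' @param lick_rate_base,lick_rate_anticipatory per-frame lick
#'   probabilities.
#' @param noise_sd baseline noise in dF/F units (0 = noise-free).
#' @param baseline_f raw-fluorescence baseline.
#' @param seed integer seed; per-session streams are derived from
#'   (seed, mouse, day).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_cells = 2511, n_mice = 1, n_days = 7,
                             track_length = 180, n_bins = 50, frame_rate = 30,
                             laps_per_session = 126,
                             block_length_range = c(12, 18),
                             reward_cm = c(RL1 = 100, RL2 = 160),
                             cue_cm = 40,
                             frac_sustained = 0.12, frac_transient = 0.25,
                             p_survival = 0.9, p_transient_two_days = 0.3,
                             day_jitter_sd = 5.9, backward_shift_cm = 1,
                             pf_amplitude = 1.2, btsp_amplitude = 3,
                             reliability = 0.85,
                             btsp_width_slope = 0.80,
                             btsp_width_intercept = 18.95,
                             com_drift_cm = 2, com_drift_decay = 0.7,
                             plateau_rate = 0.06,
                             v_run = 20, v_slow = 8, speed_jitter = 0.25,
                             pf_amplitude_cv = 0.2,
                             lick_rate_base = 0.01,
                             lick_rate_anticipatory = 0.25,
                             noise_sd = 0.05, baseline_f = 100, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_bins * (cfg$track_length / cfg$n_bins) == cfg$track_length)
  probs <- c(frac_sustained, frac_transient, p_survival,
             p_transient_two_days, reliability, lick_rate_base,
             lick_rate_anticipatory)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (laps_per_session < 1 && n_cells > 0) stop("need at least one lap")
  if (block_length_range[1] < 12 || block_length_range[2] > 18 ||
      block_length_range[1] > block_length_range[2])
    stop("block lengths must lie within [12, 18]")
  class(cfg) <- "generator_config"
  cfg
}

## deterministic velocity profile: slows approaching the reward
.velocity_profile <- function(x, reward, cfg) {
  d <- circ_diff(x, reward, cfg$track_length)   # >0 when reward ahead
  slow <- d > 0 & d < 20
  v <- rep(cfg$v_run, length(x))
  v[slow] <- cfg$v_slow +
    (cfg$v_run - cfg$v_slow) * (1 - cos(pi * d[slow] / 20)) / 2
  v
}

## one lap trajectory for a condition: frame positions and speeds; `scale`
## multiplies the whole profile (lap-to-lap speed variability)
.lap_trajectory <- function(cond, cfg, scale = 1) {
  sgrid <- seq(0.1, cfg$track_length, by = 0.2)
  v <- .velocity_profile(sgrid, cfg$reward_cm[[cond]], cfg) * scale
  tgrid <- cumsum(0.2 / v)
  n_fr <- max(1L, as.integer(floor(tgrid[length(tgrid)] * cfg$frame_rate)))
  tt <- (seq_len(n_fr) - 0.5) / cfg$frame_rate
  x <- stats::approx(c(0, tgrid), c(0, sgrid), xout = tt, rule = 2)$y
  list(x = x, v = .velocity_profile(x, cfg$reward_cm[[cond]], cfg) * scale,
       n_frames = n_fr)
}

## block structure of one session: condition label per lap
.session_blocks <- function(cfg) {
  conds <- names(cfg$reward_cm)
  lab <- character(0)
  ci <- sample.int(length(conds), 1)
  while (length(lab) < cfg$laps_per_session) {
    len <- cfg$block_length_range[1] +
      sample.int(cfg$block_length_range[2] - cfg$block_length_range[1] + 1, 1) - 1
    lab <- c(lab, rep(conds[ci], len))
    ci <- ci %% length(conds) + 1
  }
  lab[seq_len(cfg$laps_per_session)]
}

## experiment-level ground-truth assignment (classes, days, centres)
.assign_truth <- function(cfg) {
  rows <- list()
  for (mouse in seq_len(cfg$n_mice)) {
    for (cond in names(cfg$reward_cm)) {
      u <- stats::runif(cfg$n_cells)
      cls <- ifelse(u < cfg$frac_sustained, "sustained",
                    ifelse(u < cfg$frac_sustained + cfg$frac_transient,
                           "transient", "silent"))
      for (ci in which(cls != "silent")) {
        anchor <- stats::runif(1, 0, cfg$track_length)
        if (cls[ci] == "sustained") {
          first <- if (stats::runif(1) < 0.6) 1L
                   else sample.int(cfg$n_days, 1)
          days <- first
          d <- first
          while (d < cfg$n_days && stats::runif(1) < cfg$p_survival) {
            d <- d + 1L; days <- c(days, d)
          }
        } else {
          first <- sample.int(cfg$n_days, 1)
          days <- first
          if (stats::runif(1) < cfg$p_transient_two_days &&
              first < cfg$n_days)
            days <- c(first, first + 1L)
        }
        ctr <- anchor
        for (j in seq_along(days)) {
          if (j > 1) {
            ctr <- ctr - cfg$backward_shift_cm +
              stats::rnorm(1, 0, cfg$day_jitter_sd)
            ## sustained fields stay within +/-30 cm of the anchor
            off <- circ_diff(anchor, ctr, cfg$track_length)
            if (abs(off) > 30) ctr <- anchor + sign(off) * 30
            ctr <- ctr %% cfg$track_length
          }
          rows[[length(rows) + 1]] <- data.frame(
            mouse = mouse, day = days[j], condition = cond, cell = ci,
            class = cls[ci], centre_cm = ctr %% cfg$track_length,
            day_index_in_field = j)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(mouse = integer(), day = integer(),
                      condition = character(), cell = integer(),
                      class = character(), centre_cm = numeric(),
                      day_index_in_field = integer(),
                      onset_lap = integer(), induction_velocity = numeric(),
                      pf_width_cm = numeric(), btsp_amplitude = numeric(),
                      pf_amplitude = numeric()))
  do.call(rbind, rows)
}

#' Generate a synthetic multi-day experiment
#'
#' Builds one session per (mouse, day) -- raw fluorescence traces plus
#' behavior streams -- and the ground-truth table of injected fields.
#' Deterministic given `config$seed`; each session uses an RNG stream
#' derived from (seed, mouse, day) so regenerating one session does not
#' disturb the others.
#'
#' @param config a `generator_config`.
#' @return list with `sessions` (list of `session_recording`) and `truth`
#'   (data.frame: one row per cell-day-condition with centre, onset lap,
#'   induction velocity and amplitudes, plus the class label).
#' @export
generate_experiment <- function(config = generator_config()) {
  cfg <- config
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed %% .Machine$integer.max)
  truth <- .assign_truth(cfg)
  sessions <- list()
  truth_rows <- list()
  for (mouse in seq_len(cfg$n_mice)) {
    for (day in seq_len(cfg$n_days)) {
      set.seed((cfg$seed * 1009L + mouse * 101L + day) %% .Machine$integer.max)
      tr <- truth[truth$mouse == mouse & truth$day == day, , drop = FALSE]
      ses <- .generate_session(cfg, mouse, day, tr)
      sessions[[length(sessions) + 1]] <- ses$session
      if (nrow(ses$truth)) truth_rows[[length(truth_rows) + 1]] <- ses$truth
    }
  }
  truth_out <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    .assign_truth(generator_config(n_cells = 0))
  rownames(truth_out) <- NULL
  list(sessions = sessions, truth = truth_out)
}

.generate_session <- function(cfg, mouse, day, tr) {
  lap_condition <- .session_blocks(cfg)
  scales <- stats::runif(length(lap_condition), 1 - cfg$speed_jitter,
                         1 + cfg$speed_jitter)
  per_lap <- Map(.lap_trajectory, lap_condition, scale = scales,
                 MoreArgs = list(cfg = cfg))
  n_fr_lap <- vapply(per_lap, `[[`, integer(1), "n_frames")
  n_frames <- sum(n_fr_lap)
  position <- unlist(lapply(per_lap, `[[`, "x"), use.names = FALSE)
  velocity <- unlist(lapply(per_lap, `[[`, "v"), use.names = FALSE)
  lap <- rep(seq_along(per_lap), n_fr_lap)
  lap_start <- c(0L, cumsum(n_fr_lap))[seq_along(per_lap)]
  lap_mean_v <- vapply(split(velocity, lap), mean, numeric(1))
  ## licking: elevated in the three bins before the active reward
  bw <- cfg$track_length / cfg$n_bins
  rate <- rep(cfg$lick_rate_base, n_frames)
  for (cond in names(cfg$reward_cm)) {
    rz <- cfg$reward_cm[[cond]]
    ahead <- circ_diff(position, rz, cfg$track_length)
    antic <- lap_condition[lap] == cond & ahead > 0 & ahead <= 3 * bw
    rate[antic] <- cfg$lick_rate_anticipatory
  }
  licks <- as.integer(stats::runif(n_frames) < rate)
  ## fluorescence
  dff <- matrix(0, max(cfg$n_cells, 1), n_frames)
  out_truth <- list()
  if (nrow(tr)) for (i in seq_len(nrow(tr))) {
    cond <- tr$condition[i]
    cond_laps <- which(lap_condition == cond)
    if (!length(cond_laps)) next
    n_cl <- length(cond_laps)
    reconstituted <- tr$day_index_in_field[i] > 1
    onset_local <- if (reconstituted)
      min(1L + stats::rgeom(1, 0.4), max(1L, n_cl %/% 3))
    else sample.int(max(1L, floor(0.4 * n_cl)), 1)
    vel <- lap_mean_v[cond_laps[onset_local]]
    width <- cfg$btsp_width_slope * vel + cfg$btsp_width_intercept
    sg <- width / (2 * sqrt(2 * log(2)))   # width = full width at half max
    ## active post-onset laps: the 5 after induction always fire, the rest
    ## with the configured reliability
    post <- seq(onset_local + 1, length.out = max(0, n_cl - onset_local))
    active <- logical(n_cl); active[onset_local] <- TRUE
    if (length(post)) {
      forced <- post[seq_len(min(5, length(post)))]
      active[forced] <- TRUE
      rest <- setdiff(post, forced)
      active[rest] <- stats::runif(length(rest)) < cfg$reliability
    }
    ## plateau-amplitude laps at the configured per-lap rate
    amp <- ifelse(active,
                  cfg$pf_amplitude *
                    exp(stats::rnorm(n_cl, 0, cfg$pf_amplitude_cv)),
                  0)
    n_extra <- max(0, round(cfg$plateau_rate * n_cl) - 1)
    big <- which(active)[-1]
    if (length(big) && n_extra > 0)
      amp[sample(big, min(n_extra, length(big)))] <- cfg$btsp_amplitude
    amp[onset_local] <- cfg$btsp_amplitude
    drift <- numeric(n_cl)
    if (length(post))
      drift[post] <- -cfg$com_drift_cm *
        cfg$com_drift_decay^(seq_along(post) - 1)
    for (j in which(active)) {
      lp <- cond_laps[j]
      idx <- (lap_start[lp] + 1):(lap_start[lp] + n_fr_lap[lp])
      ctr <- (tr$centre_cm[i] + drift[j]) %% cfg$track_length
      d <- circ_dist(position[idx], ctr, cfg$track_length)
      dff[tr$cell[i], idx] <- dff[tr$cell[i], idx] +
        amp[j] * exp(-d^2 / (2 * sg^2))
    }
    out_truth[[length(out_truth) + 1]] <- data.frame(
      tr[i, ], onset_lap = cond_laps[onset_local],
      induction_velocity = vel, pf_width_cm = width,
      btsp_amplitude = cfg$btsp_amplitude, pf_amplitude = cfg$pf_amplitude)
  }
  if (cfg$n_cells > 0 && cfg$noise_sd > 0)
    dff <- dff + matrix(stats::rnorm(length(dff), 0, cfg$noise_sd),
                        nrow(dff), ncol(dff))
  traces <- cfg$baseline_f * (1 + dff)
  if (cfg$n_cells == 0) traces <- matrix(numeric(0), 0, n_frames)
  session <- structure(list(
    traces = traces, position = position, velocity = velocity,
    licks = licks, lap = lap, lap_condition = lap_condition,
    reward_cm = cfg$reward_cm, cue_cm = cfg$cue_cm,
    frame_rate = cfg$frame_rate, track_length = cfg$track_length,
    mouse = mouse, day = day, schema_version = "1.0"),
    class = "session_recording")
  truth <- if (length(out_truth)) do.call(rbind, out_truth) else
    tr[0, , drop = FALSE]
  list(session = session, truth = truth)
}

#' Inject a BTSP-like induction event into a lap x bin activity map
#'
#' Adds a plateau-amplitude event on the induction lap and a Gaussian
#' field of width `slope * velocity + intercept` on the subsequent laps,
#' whose centre of mass starts shifted backward and relaxes geometrically
#' -- the generative counterpart of the four induction criteria.
#'
#' @param map lap x bin activity matrix to modify.
#' @param lap induction lap (row index).
#' @param centre_cm field centre in cm.
#' @param velocity running speed in the induction lap (cm/s), > 0.
#' @param amplitude induction-event dF/F (0 = no injection).
#' @param post_amplitude dF/F of subsequent field events.
#' @param slope,intercept width regression coefficients.
#' @param drift_cm,drift_decay initial backward COM offset and decay.
#' @param n_post subsequent active laps to inject (>= 3 of the first 5 are
#'   needed by the detector).
#' @param track_length belt length in cm.
#' @return list with `map` (modified) and `event` (one-row ground-truth
#'   data.frame, or empty when `amplitude` is 0).
#' @export
inject_btsp_event <- function(map, lap, centre_cm, velocity,
                              amplitude = 3, post_amplitude = 1.2,
                              slope = 0.80, intercept = 18.95,
                              drift_cm = 2, drift_decay = 0.7,
                              n_post = 10, track_length = 180) {
  if (lap < 1 || lap > nrow(map)) stop("induction lap outside the session")
  stopifnot(velocity > 0)
  empty <- data.frame(lap = integer(), centre_cm = numeric(),
                      velocity = numeric(), amplitude = numeric(),
                      pf_width_cm = numeric())
  if (amplitude <= 0) return(list(map = map, event = empty))
  nb <- ncol(map)
  ctr <- bin_centers(nb, track_length)
  width <- slope * velocity + intercept
  sg <- width / (2 * sqrt(2 * log(2)))     # width = full width at half max
  bump <- function(c0, a)
    a * exp(-circ_dist(ctr, c0 %% track_length, track_length)^2 / (2 * sg^2))
  map[lap, ] <- pmax(map[lap, ], bump(centre_cm, amplitude), na.rm = TRUE)
  post <- seq(lap + 1, length.out = max(0, min(n_post, nrow(map) - lap)))
  for (j in seq_along(post))
    map[post[j], ] <- pmax(map[post[j], ],
                           bump(centre_cm - drift_cm * drift_decay^(j - 1),
                                post_amplitude), na.rm = TRUE)
  list(map = map,
       event = data.frame(lap = lap, centre_cm = centre_cm,
                          velocity = velocity, amplitude = amplitude,
                          pf_width_cm = width))
}

#' Synthesize a membrane-potential trace with plateaus and spikes
#'
#' Builds a current-clamp-like Vm series at the given sampling rate:
#' resting baseline, depolarized plateaus (ramped onset slower than the
#' spike dV/dt threshold) crossing -35 mV for the specified durations,
#' spikes riding on the plateaus, and optional baseline spikes whose
#' upstroke starts near -50 mV (so the printed spike-threshold baseline
#' correction is neutral).
#'
#' @param plateau_spec data.frame with columns `onset_s` and `duration_ms`
#'   (may be empty).
#' @param duration_s total trace duration.
#' @param sampling_rate in Hz.
#' @param baseline_mv resting potential.
#' @param plateau_mv plateau level (> -35).
#' @param spikes_per_plateau spikes added on each plateau.
#' @param n_baseline_spikes spikes added away from plateaus.
#' @param noise_sd_mv Gaussian noise s.d. (0 = clean).
#' @return numeric Vm vector (mV).
#' @export
synthesize_vm_trace <- function(plateau_spec, duration_s = 5,
                                sampling_rate = 20000, baseline_mv = -65,
                                plateau_mv = -30, spikes_per_plateau = 2,
                                n_baseline_spikes = 2, noise_sd_mv = 0) {
  n <- round(duration_s * sampling_rate)
  vm <- rep(baseline_mv, n)
  if (nrow(plateau_spec)) {
    stopifnot(all(plateau_spec$duration_ms > 0))
    o <- order(plateau_spec$onset_s)
    ps <- plateau_spec[o, , drop = FALSE]
    ends <- ps$onset_s + ps$duration_ms / 1000
    if (any(ps$onset_s[-1] < ends[-nrow(ps)] + 0.02))
      stop("overlapping plateau specifications")
    ramp_n <- round(0.010 * sampling_rate)       # 10-ms ramps (~3.5 V/s)
    for (i in seq_len(nrow(ps))) {
      a <- round(ps$onset_s[i] * sampling_rate) + 1
      b <- min(n, a + round(ps$duration_ms[i] / 1000 * sampling_rate) - 1)
      vm[a:b] <- plateau_mv
      up <- max(1, a - ramp_n):(a - 1)
      if (length(up) && a > 1)
        vm[up] <- pmax(vm[up], seq(baseline_mv, plateau_mv,
                                   length.out = length(up)))
      dn <- (b + 1):min(n, b + ramp_n)
      if (b < n)
        vm[dn] <- pmax(vm[dn], seq(plateau_mv, baseline_mv,
                                   length.out = length(dn)))
      if (spikes_per_plateau > 0) {
        at <- round(seq(a + 0.02 * sampling_rate, b - 0.005 * sampling_rate,
                        length.out = spikes_per_plateau))
        for (s in at[at > 0 & at < b]) vm <- .add_spike(vm, s, sampling_rate,
                                                        onset_mv = plateau_mv)
      }
    }
  }
  if (n_baseline_spikes > 0 && n > sampling_rate %/% 2) {
    free <- round(seq(0.1 * n, 0.95 * n, length.out = n_baseline_spikes))
    occupied <- vm > baseline_mv + 1
    for (s in free) {
      win <- max(1, s - 0.03 * sampling_rate):min(n, s + 0.03 * sampling_rate)
      if (any(occupied[win])) next
      ## slow pre-depolarization to -50 mV, then the fast upstroke
      pre <- round(0.005 * sampling_rate)
      vm[(s - pre):s] <- seq(baseline_mv, -50, length.out = pre + 1)
      vm <- .add_spike(vm, s, sampling_rate, onset_mv = -50,
                       settle_mv = baseline_mv)
    }
  }
  if (noise_sd_mv > 0) vm <- vm + stats::rnorm(n, 0, noise_sd_mv)
  vm
}

## 1-ms upstroke to +20 mV (~70 V/s), 2-ms decay back to settle level
.add_spike <- function(vm, at, fs, onset_mv, settle_mv = onset_mv) {
  up <- round(0.001 * fs); dn <- round(0.002 * fs)
  n <- length(vm)
  a <- at; b <- min(n, at + up); c2 <- min(n, b + dn)
  vm[a:b] <- seq(onset_mv, 20, length.out = b - a + 1)
  if (c2 > b) vm[(b + 1):c2] <- seq(20, settle_mv, length.out = c2 - b + 1)[-1]
  vm
}
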
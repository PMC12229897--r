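## Generative models of place-cell stabilization: three-pool kinetic model,
## cascade-type state model and the progressive-stabilization alternative.

## ---------------------------------------------------------------- three-pool

#' Rate constants of the three-pool kinetic model
#'
#' Activation rates are set so one 1-h activation converts the observed
#' day-1 place-cell fraction out of the available pool, split between the
#' transient and sustained pools by the double-exponential amplitude
#' fractions; decay rates are the reciprocals of the fitted time constants.
#' The printed logarithm of a fraction is negative, so magnitudes are used
#' (pools must deplete during activation).
#'
#' @param day1_total place cells on day 1.
#' @param Amp1,Amp2 fast/slow amplitudes of the cohort-decay fit (cells).
#' @param tau1,tau2 fast/slow time constants (days).
#' @param A0 available population.
#' @return list with `k1`, `k2` (per hour), `k3`, `k4` (per day).
#' @export
three_pool_rates <- function(day1_total, Amp1, Amp2, tau1 = 0.67, tau2 = 4.6,
                             A0 = 2511) {
  stopifnot(day1_total > 0, tau1 > 0, tau2 > 0)
  if (day1_total >= A0) stop("day-1 place-cell count must be below the available population")
  ktot <- abs(log((A0 - day1_total) / A0))
  list(k1 = ktot * Amp1 / (Amp1 + Amp2),
       k2 = ktot * Amp2 / (Amp1 + Amp2),
       k3 = 1 / tau1, k4 = 1 / tau2)
}

#' Configuration of the three-pool model
#'
#' @param A0 available pyramidal cells.
#' @param day1_total expected day-1 place-cell count.
#' @param Amp1,Amp2 cohort-fit amplitudes (cells).
#' @param tau1,tau2 decay time constants (days).
#' @param b_factor multiplier relating the sustained daily scaling to the
#'   transient one (`b = a * b_factor`; the model's one free parameter).
#' @param expected_daily_totals desired total place cells per day (scalar or
#'   length `n_days`).
#' @param n_days days to simulate.
#' @param dt_activation_h,n_activation_steps activation-phase Euler step (h)
#'   and count (0.01 h x 100 = 1 h).
#' @param n_decay_steps decay-phase Euler steps; one decay phase integrates
#'   the per-day decay rates over one day.
#' @return list of class `three_pool_config`.
#' @export
three_pool_config <- function(A0 = 2511, day1_total = 767,
                              Amp1 = 590, Amp2 = 177,
                              tau1 = 0.67, tau2 = 4.6, b_factor = 0.6,
                              expected_daily_totals = 767, n_days = 7,
                              dt_activation_h = 0.01, n_activation_steps = 100,
                              n_decay_steps = 2300) {
  cfg <- as.list(environment())
  if (length(cfg$expected_daily_totals) == 1)
    cfg$expected_daily_totals <- rep(cfg$expected_daily_totals, n_days)
  class(cfg) <- "three_pool_config"
  cfg
}

#' Simulate the three-pool kinetic model
#'
#' Each day has an activation phase (1 h, forward Euler with the per-hour
#' rates k1, k2 scaled daily by `a = 1 - (S_d + T_d)/expected total` and
#' `b = a * b_factor`) during which available cells convert to transient
#' and sustained place cells, followed by a decay phase in which both pools
#' decay back to the available population with per-day rates k3, k4. The
#' sum [A]+[T]+[S] is conserved. The day-1 cohort is tracked separately
#' through the decay phases to give survivor counts.
#'
#' @param config a `three_pool_config`.
#' @return list with `daily` (data.frame: day, A, T, S, total at the end of
#'   each activation), `cohort_day1` (day-1 cohort survivors per day),
#'   `rates`, `conservation_error`.
#' @export
three_pool_simulate <- function(config = three_pool_config()) {
  k <- three_pool_rates(config$day1_total, config$Amp1, config$Amp2,
                        config$tau1, config$tau2, config$A0)
  A <- config$A0; Tt <- 0; S <- 0
  coT <- coS <- 0
  nd <- config$n_days
  daily <- data.frame(day = seq_len(nd), A = NA_real_, T = NA_real_,
                      S = NA_real_, total = NA_real_)
  cohort <- numeric(nd)
  cons_err <- 0
  for (d in seq_len(nd)) {
    a <- 1 - (S + Tt) / config$expected_daily_totals[d]
    b <- a * config$b_factor
    kk1 <- k$k1 * a; kk2 <- k$k2 * b
    dt <- config$dt_activation_h
    for (s in seq_len(config$n_activation_steps)) {
      dA <- -(kk1 + kk2) * A
      Tt <- Tt + kk1 * A * dt
      S <- S + kk2 * A * dt
      A <- A + dA * dt
      if (A < 0) stop("negative pool during activation; step too large")
    }
    if (d == 1) { coT <- Tt; coS <- S }
    daily[d, 2:5] <- c(A, Tt, S, Tt + S)
    cohort[d] <- coT + coS
    cons_err <- max(cons_err, abs(A + Tt + S - config$A0))
    dtd <- 1 / config$n_decay_steps         # one day of decay per cycle
    for (s in seq_len(config$n_decay_steps)) {
      dT <- -k$k3 * Tt; dS <- -k$k4 * S
      A <- A - (dT + dS) * dtd
      Tt <- Tt + dT * dtd
      S <- S + dS * dtd
      coT <- coT * (1 - k$k3 * dtd)
      coS <- coS * (1 - k$k4 * dtd)
    }
    cons_err <- max(cons_err, abs(A + Tt + S - config$A0))
  }
  list(daily = daily, cohort_day1 = cohort, rates = k,
       conservation_error = cons_err)
}

#' Fit the free daily-scaling parameter b of the three-pool model
#'
#' Scans the `b_factor` multiplier to minimize the mean squared error
#' between the model's daily transient/sustained pool sizes and observed
#' counts.
#'
#' @param config a `three_pool_config` (its `b_factor` is ignored).
#' @param observed data.frame with columns `day`, `pool` ("T" or "S") and
#'   `count`.
#' @param interval search interval for the multiplier.
#' @return list with `b_factor`, `mse`, `residuals`, `n`.
#' @export
three_pool_fit_b <- function(config, observed, interval = c(0, 2)) {
  stopifnot(all(c("day", "pool", "count") %in% names(observed)))
  mse_of <- function(b) {
    config$b_factor <- b
    sim <- three_pool_simulate(config)$daily
    pred <- ifelse(observed$pool == "T", sim$T[observed$day],
                   sim$S[observed$day])
    mean((pred - observed$count)^2)
  }
  opt <- stats::optimize(mse_of, interval = interval)
  config$b_factor <- opt$minimum
  sim <- three_pool_simulate(config)$daily
  pred <- ifelse(observed$pool == "T", sim$T[observed$day],
                 sim$S[observed$day])
  list(b_factor = opt$minimum, mse = opt$objective,
       residuals = observed$count - pred, n = nrow(observed))
}

## ------------------------------------------------------------------ cascade

#' Cascade-model parameter formulas
#'
#' The per-state decay probability `q_i`, plasticity rate `alpha_i`,
#' daily global modulation `beta_k` and history-modulation amplitude
#' `gamma_l` of the cascade-type state model.
#'
#' @param i state index (days of place-field activity).
#' @param k day index.
#' @param l days the previous field was sustained.
#' @name cascade_parameters
NULL

#' @rdname cascade_parameters
#' @export
cascade_q <- function(i) 0.5353 * exp(-0.3327 * (i - 1)) + 0.2912

#' @rdname cascade_parameters
#' @export
cascade_alpha <- function(i) 6.6259 * (1 - cascade_q(i))^2

#' @rdname cascade_parameters
#' @export
cascade_beta <- function(k) 0.4927 * exp(-0.1289 * (k - 1)) +
  0.7032 * exp(-1.1846 * (k - 1))

#' @rdname cascade_parameters
#' @export
cascade_gamma <- function(l) (1 + pmin(l / 6, 1)) / (1 - 0.5 * pmin(l / 6, 1))

#' Salience and history (location) modulation weights
#'
#' Salience multiplies the plasticity probability by `delta` inside the
#' salient zones and is normalized by `1/(1 + (delta - 1) s)` (s = salient
#' fraction of the belt) so its track average is exactly 1. The history
#' weight multiplies by `gamma` within 30 cm of the previous field and is
#' normalized by `1/(1 + (gamma - 1)/3)`; cells without a previous field
#' have `Loc = 1` everywhere.
#'
#' @param x positions in cm (e.g. bin locations).
#' @param zones matrix with one salient interval (cm) per row.
#' @param delta salience modulation factor.
#' @param prev_pf previous field location in cm, or `NULL`.
#' @param gamma history modulation amplitude (from [cascade_gamma()]).
#' @param window history window in cm.
#' @param track_length belt length in cm.
#' @return list with `sal` and `loc` weight vectors over `x`.
#' @export
salience_and_history_weights <- function(x, zones = rbind(c(30, 60), c(120, 150)),
                                         delta = 1.7, prev_pf = NULL,
                                         gamma = 1, window = 30,
                                         track_length = 180) {
  inz <- rep(FALSE, length(x))
  if (!is.null(zones))
    for (r in seq_len(nrow(zones)))
      inz <- inz | (x >= zones[r, 1] & x <= zones[r, 2])
  s <- mean(inz)
  sal <- ifelse(inz, delta, 1) / (1 + (delta - 1) * s)
  ## the printed normalizer 1/(1 + (gamma - 1)/3) is the continuous-track
  ## value (the 60-cm window is one third of the belt); on a binned track
  ## the empirical window fraction keeps the mean-1 identity exact
  loc <- if (is.null(prev_pf)) rep(1, length(x)) else {
    near <- circ_dist(x, prev_pf, track_length) <= window
    ifelse(near, gamma, 1) / (1 + (gamma - 1) * mean(near))
  }
  list(sal = sal, loc = loc)
}

#' Configuration of the cascade-type state model
#'
#' @param n_cells cells per simulation.
#' @param n_days days per simulation.
#' @param n_bins spatial bins N.
#' @param track_length belt length L in cm.
#' @param zones salient zones (cm intervals, one per row).
#' @param delta salience modulation factor.
#' @param init_state1_fraction fraction initialized to unreliable state 1
#'   (the rest start in unreliable state 0).
#' @param f_reliable reconstitution probability of reliable cells.
#' @param alpha_scale multiplier on the plasticity rate alpha_i (1 = the
#'   printed formula; 0 switches recruitment off).
#' @param indexing `"destination"` uses the entered state's parameters
#'   (alpha_{i+1}) for recruitment from resting state i; `"source"` uses
#'   alpha_i. Destination indexing reproduces the observed daily counts.
#' @param history_window cm window of the history weight.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(n_cells = 2511, n_days = 7, n_bins = 50,
                           track_length = 180,
                           zones = rbind(c(30, 60), c(120, 150)),
                           delta = 1.7, init_state1_fraction = 0.12,
                           f_reliable = 1, alpha_scale = 1,
                           indexing = c("destination", "source"),
                           history_window = 30) {
  cfg <- as.list(environment())
  cfg$indexing <- match.arg(indexing)
  class(cfg) <- "cascade_config"
  cfg
}

#' Simulate the cascade-type state model
#'
#' Cells occupy states counting their days of place-field activity and
#' rest between sessions in either a reliable or an unreliable pool. Each
#' day: (activation) reliable cells reconstitute their field with
#' probability `f_reliable`, keeping its location; unreliable cells at
#' state i are recruited with probability
#' `p_i = 1 - prod_j [1 - r Sal(x_j) Loc(x_j)]`,
#' `r = 1 - (1 - alpha beta_k)^(1/N)`, drawing a new location with
#' probability proportional to `Sal * Loc`; (decay) every active cell at
#' state i moves to the unreliable pool with probability `q_i`, otherwise
#' to the reliable pool. State indices never decrease. `alpha beta_k` is
#' clamped to [0, 1) before the N-th root.
#'
#' @param config a `cascade_config`.
#' @param n_reps number of independent replicates.
#' @param keep_cells keep the last replicate's per-cell activity and
#'   location logs (for recount checks).
#' @return list of class `cascade_sim`: `daily_counts` (replicate x day
#'   active place cells), `config`, and per-replicate summary accumulators
#'   (`days_active`, `reappearance`, `class_counts`, `density`) used by
#'   [cascade_summaries()]; with `keep_cells`, also `activity` and
#'   `locations` for the last replicate.
#' @export
cascade_simulate <- function(config = cascade_config(), n_reps = 1,
                             keep_cells = FALSE) {
  nc <- config$n_cells; nd <- config$n_days; N <- config$n_bins
  L <- config$track_length
  xj <- (1:N) * L / N                    # printed bin locations x_j = j L / N
  w0 <- salience_and_history_weights(xj, config$zones, config$delta,
                                     track_length = L)
  Sal <- w0$sal
  daily_counts <- matrix(0L, n_reps, nd)
  days_active <- matrix(0, n_reps, nd)   # cells active exactly n days
  reap_num <- reap_den <- matrix(0, n_reps, nd)  # by prior days active
  sust_daily <- trans_daily <- matrix(0, n_reps, nd)
  dens <- matrix(0, n_reps, N)
  act_log <- loc_log <- NULL
  for (rep in seq_len(n_reps)) {
    state <- ifelse(stats::runif(nc) < config$init_state1_fraction, 1L, 0L)
    reliable <- rep(FALSE, nc)
    pf <- rep(NA_real_, nc)
    lsus <- rep(0L, nc)
    activity <- matrix(FALSE, nc, nd)
    locations <- matrix(NA_real_, nc, nd)
    for (k in seq_len(nd)) {
      b <- cascade_beta(k)
      newly <- rep(FALSE, nc)
      newloc <- pf
      newly[reliable & stats::runif(nc) < config$f_reliable] <- TRUE
      unrel <- which(!reliable)
      if (length(unrel)) {
        st <- state[unrel]
        al <- config$alpha_scale *
          if (config$indexing == "destination") cascade_alpha(st + 1)
          else cascade_alpha(pmax(st, 1))
        ab <- pmin(pmax(al * b, 0), 1 - 1e-12)
        r <- 1 - (1 - ab)^(1 / N)
        haspf <- !is.na(pf[unrel])
        p <- numeric(length(unrel))
        if (any(!haspf)) {
          base_log <- rowSums(log1p(-outer(r[!haspf], Sal)))
          p[!haspf] <- 1 - exp(base_log)
        }
        if (any(haspf)) {
          ix <- unrel[haspf]
          g <- cascade_gamma(lsus[ix])
          D <- outer(pf[ix], xj, circ_dist, track_length = L) <=
            config$history_window
          Loc <- (1 + (g - 1) * D) / (1 + (g - 1) * rowMeans(D))
          W <- sweep(Loc, 2, Sal, `*`)
          p[haspf] <- 1 - exp(rowSums(log1p(-pmin(r[haspf] * W, 1 - 1e-15))))
        }
        rec <- stats::runif(length(unrel)) < p
        if (any(rec)) {
          fresh <- unrel[rec & !haspf]    # shared Sal-only location weights
          if (length(fresh))
            newloc[fresh] <- xj[sample.int(N, length(fresh), replace = TRUE,
                                           prob = Sal)]
          for (cell in unrel[rec & haspf]) {
            g <- cascade_gamma(lsus[cell])
            near <- circ_dist(pf[cell], xj, track_length = L) <=
              config$history_window
            w <- Sal * ifelse(near, g, 1) / (1 + (g - 1) * mean(near))
            newloc[cell] <- xj[sample.int(N, 1, prob = w)]
          }
          newly[unrel[rec]] <- TRUE
        }
      }
      act <- which(newly)
      if (length(act)) {
        moved <- !is.na(pf[act]) &
          circ_dist(newloc[act], pf[act], track_length = L) <=
            config$history_window
        lsus[act] <- ifelse(moved | (reliable[act] & !is.na(pf[act])),
                            lsus[act] + 1L, 1L)
        pf[act] <- newloc[act]
        state[act] <- state[act] + 1L
        activity[act, k] <- TRUE
        locations[act, k] <- pf[act]
        ## decay phase
        q <- cascade_q(state[act])
        to_unrel <- stats::runif(length(act)) < q
        reliable[act] <- !to_unrel
      }
      daily_counts[rep, k] <- length(act)
    }
    ## replicate summaries
    nda <- rowSums(activity)
    days_active[rep, ] <- tabulate(nda[nda > 0], nbins = nd)
    for (k in if (nd >= 3) 3:nd else integer(0)) {
      gap <- !activity[, k - 1]
      prior <- rowSums(activity[, seq_len(k - 2), drop = FALSE])
      for (m in seq_len(nd)) {
        den <- gap & prior == m
        reap_den[rep, m] <- reap_den[rep, m] + sum(den)
        reap_num[rep, m] <- reap_num[rep, m] + sum(den & activity[, k])
      }
    }
    ## sustained = active > 2 days so far, transient = <= 2 (counts rule)
    cum <- t(apply(activity, 1, cumsum))
    for (k in seq_len(nd)) {
      on <- activity[, k]
      sust_daily[rep, k] <- sum(on & cum[, k] > 2)
      trans_daily[rep, k] <- sum(on & cum[, k] <= 2)
    }
    locs <- locations[!is.na(locations)]
    dens[rep, ] <- tabulate(match(round(locs, 6), round(xj, 6)), nbins = N)
    if (keep_cells && rep == n_reps) { act_log <- activity; loc_log <- locations }
  }
  structure(list(daily_counts = daily_counts, days_active = days_active,
                 reappearance_num = reap_num, reappearance_den = reap_den,
                 sustained_daily = sust_daily, transient_daily = trans_daily,
                 density = dens, config = config,
                 activity = act_log, locations = loc_log),
            class = "cascade_sim")
}

#' Summaries of a cascade (or progressive) simulation
#'
#' Replicate-averaged (mean and s.e.m.) distribution of days with field
#' activity, probability of reappearing after one missed day as a function
#' of prior active days, sustained/transient counts per day, and field
#' density over bins.
#'
#' @param sim a `cascade_sim` from [cascade_simulate()] or
#'   [progressive_simulate()].
#' @return list of data.frames: `days_active`, `reappearance`,
#'   `class_counts`, `density`, `daily_counts`.
#' @export
cascade_summaries <- function(sim) {
  nr <- nrow(sim$daily_counts)
  msem <- function(m) list(mean = colMeans(m),
                           sem = apply(m, 2, stats::sd) / sqrt(nr))
  da <- msem(sim$days_active / rowSums(sim$days_active))
  prop <- sim$reappearance_num / ifelse(sim$reappearance_den > 0,
                                        sim$reappearance_den, NA)
  rp_mean <- colMeans(prop, na.rm = TRUE)
  rp_sem <- apply(prop, 2, stats::sd, na.rm = TRUE) / sqrt(nr)
  nd <- ncol(sim$daily_counts)
  list(
    days_active = data.frame(n_days = seq_len(nd), proportion = da$mean,
                             sem = da$sem),
    reappearance = data.frame(prior_days_active = seq_len(ncol(prop)),
                              probability = rp_mean, sem = rp_sem),
    class_counts = data.frame(day = seq_len(nd),
                              sustained = colMeans(sim$sustained_daily),
                              transient = colMeans(sim$transient_daily)),
    density = data.frame(bin = seq_len(ncol(sim$density)),
                         mean_count = colMeans(sim$density)),
    daily_counts = data.frame(day = seq_len(nd),
                              mean = colMeans(sim$daily_counts),
                              sem = apply(sim$daily_counts, 2, stats::sd) /
                                sqrt(nr)))
}

## -------------------------------------------------------------- progressive

#' Simulate the progressive-stabilization model
#'
#' Two macro-states: "no PF" and "active PF" with a stability index i that
#' counts consecutive days of presence. Activation: no-PF cells become
#' active at state 1 with probability `p1_scale * beta_k`; active cells
#' progress i -> i+1 keeping their field (probability `f` = 1). Decay:
#' active cells at state i revert to no-PF with probability
#' `q_i = q_base^i`.
#'
#' @param n_cells,n_days,n_bins,track_length as in [cascade_config()].
#' @param p1_scale recruitment scale (`p_1 = p1_scale * beta_k`).
#' @param q_base base of the power-law decay probability.
#' @param n_reps replicates.
#' @param keep_cells keep the last replicate's logs.
#' @return list of class `cascade_sim` (same summary fields as
#'   [cascade_simulate()]).
#' @export
progressive_simulate <- function(n_cells = 2511, n_days = 7, n_bins = 50,
                                 track_length = 180, p1_scale = 0.3186,
                                 q_base = 0.67, n_reps = 1,
                                 keep_cells = FALSE) {
  xj <- (1:n_bins) * track_length / n_bins
  daily_counts <- matrix(0L, n_reps, n_days)
  days_active <- matrix(0, n_reps, n_days)
  reap_num <- reap_den <- matrix(0, n_reps, n_days)
  sust_daily <- trans_daily <- matrix(0, n_reps, n_days)
  dens <- matrix(0, n_reps, n_bins)
  act_log <- loc_log <- NULL
  for (rep in seq_len(n_reps)) {
    state <- rep(0L, n_cells)            # 0 = no PF; i >= 1 = active PF
    pf <- rep(NA_real_, n_cells)
    activity <- matrix(FALSE, n_cells, n_days)
    locations <- matrix(NA_real_, n_cells, n_days)
    for (k in seq_len(n_days)) {
      p1 <- min(p1_scale * cascade_beta(k), 1)
      nopf <- state == 0L
      recruit <- nopf & stats::runif(n_cells) < p1
      pf[recruit] <- xj[sample.int(n_bins, sum(recruit), replace = TRUE)]
      state[recruit] <- 1L
      progress <- !nopf                   # active cells move i -> i+1
      state[progress] <- state[progress] + 1L
      on <- recruit | progress
      activity[on, k] <- TRUE
      locations[on, k] <- pf[on]
      daily_counts[rep, k] <- sum(on)
      ## decay
      act <- which(on)
      q <- q_base^state[act]
      drop <- stats::runif(length(act)) < q
      state[act[drop]] <- 0L
      pf[act[drop]] <- NA_real_
    }
    nda <- rowSums(activity)
    days_active[rep, ] <- tabulate(nda[nda > 0], nbins = n_days)
    for (k in if (n_days >= 3) 3:n_days else integer(0)) {
      gap <- !activity[, k - 1]
      prior <- rowSums(activity[, seq_len(k - 2), drop = FALSE])
      for (m in seq_len(n_days)) {
        den <- gap & prior == m
        reap_den[rep, m] <- reap_den[rep, m] + sum(den)
        reap_num[rep, m] <- reap_num[rep, m] + sum(den & activity[, k])
      }
    }
    cum <- t(apply(activity, 1, cumsum))
    for (k in seq_len(n_days)) {
      on <- activity[, k]
      sust_daily[rep, k] <- sum(on & cum[, k] > 2)
      trans_daily[rep, k] <- sum(on & cum[, k] <= 2)
    }
    locs <- locations[!is.na(locations)]
    dens[rep, ] <- tabulate(match(round(locs, 6), round(xj, 6)),
                            nbins = n_bins)
    if (keep_cells && rep == n_reps) { act_log <- activity; loc_log <- locations }
  }
  structure(list(daily_counts = daily_counts, days_active = days_active,
                 reappearance_num = reap_num, reappearance_den = reap_den,
                 sustained_daily = sust_daily, transient_daily = trans_daily,
                 density = dens,
                 config = list(model = "progressive", n_cells = n_cells,
                               n_days = n_days),
                 activity = act_log, locations = loc_log),
            class = "cascade_sim")
}
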
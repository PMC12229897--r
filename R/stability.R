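## Multi-day place-field stability: day-to-day shifts, consistency chains,
## transient/sustained classification, cohort decay fits, memoryless-random
## expectations and the per-mouse stability index.

#' Signed day-to-day place-field shift
#'
#' Signed circular difference between two field locations on the belt,
#' wrapped into `(-90, 90]` cm for a 180-cm track. Negative shifts are
#' backward relative to the running direction.
#'
#' @param loc_a,loc_b field locations in cm, in `[0, track_length)`.
#' @param track_length belt length in cm.
#' @return signed shift in cm (`loc_b` relative to `loc_a`).
#' @export
pf_shift <- function(loc_a, loc_b, track_length = 180) {
  if (any(loc_a < 0 | loc_a >= track_length | loc_b < 0 | loc_b >= track_length))
    stop("locations must lie in [0, track_length)")
  circ_diff(loc_a, loc_b, track_length)
}

#' Gaussian fit of a shift distribution
#'
#' Fits a Gaussian function to the histogram of day-to-day shifts and
#' reports the centre, s.d. and the 3-s.d. jitter bound used to choose the
#' consistency window.
#'
#' @param shifts numeric vector of signed shifts in cm (>= 50 values).
#' @param bin_width histogram bin width in cm.
#' @return list with `mu`, `sigma`, `three_sd`, `converged`.
#' @export
fit_shift_gaussian <- function(shifts, bin_width = 5) {
  stopifnot(length(shifts) >= 50)
  if (stats::sd(shifts) == 0)
    return(list(mu = shifts[1], sigma = 0, three_sd = 0, converged = TRUE))
  br <- seq(floor(min(shifts)) - bin_width, ceiling(max(shifts)) + bin_width,
            by = bin_width)
  h <- graphics::hist(shifts, breaks = br, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sg^2)), data = df,
                      start = list(a = max(df$y), mu = mean(shifts),
                                   sg = stats::sd(shifts))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian histogram fit failed; falling back to sample moments")
    return(list(mu = mean(shifts), sigma = stats::sd(shifts),
                three_sd = 3 * stats::sd(shifts), converged = FALSE))
  }
  co <- coef(fit)
  list(mu = unname(co["mu"]), sigma = abs(unname(co["sg"])),
       three_sd = 3 * abs(unname(co["sg"])), converged = TRUE)
}

#' Build per-cell place-field consistency chains
#'
#' For each (mouse, condition, cell), a chain starts on the first day a
#' field appears and extends over consecutive days on which the cell keeps
#' a field within `window` cm (circular) of its first-day location. A
#' missed day or an out-of-window jump ends the chain.
#'
#' @param pf table of detected fields (columns mouse, day, condition, cell,
#'   pf_location_cm), as produced by [detect_place_fields()].
#' @param window consistency window in cm (+/- 30 default, +/- 20 alternate).
#' @param track_length belt length in cm.
#' @return data.frame with one row per (mouse, condition, cell): first_day,
#'   length (days with a consistent field from the first day), first_location,
#'   n_days_with_pf, and `locations` (per-day locations, comma-separated,
#'   NA for days without a field).
#' @export
build_consistency_chains <- function(pf, window = 30, track_length = 180) {
  stopifnot(all(c("mouse", "day", "condition", "cell", "pf_location_cm")
                %in% names(pf)))
  key <- interaction(pf$mouse, pf$condition, pf$cell, drop = TRUE)
  rows <- split(seq_len(nrow(pf)), key)
  out <- lapply(rows, function(ix) {
    d <- pf$day[ix]; loc <- pf$pf_location_cm[ix]
    o <- order(d); d <- d[o]; loc <- loc[o]
    first <- d[1]
    len <- 1L
    while (len < length(d) &&
           d[len + 1] == first + len &&
           circ_dist(loc[len + 1], loc[1], track_length) <= window)
      len <- len + 1L
    data.frame(mouse = pf$mouse[ix[1]], condition = pf$condition[ix[1]],
               cell = pf$cell[ix[1]], first_day = first, length = len,
               first_location = loc[1], n_days_with_pf = length(d),
               locations = paste(sprintf("%d:%.1f", d, loc), collapse = ","))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cohort consistent place-cell counts
#'
#' @param chains output of [build_consistency_chains()].
#' @param n_days number of experimental days.
#' @return matrix `counts[c, d]`: number of cells first appearing on day c
#'   whose chain still includes day d (d >= c). Counts are non-increasing
#'   along each row.
#' @export
cohort_counts <- function(chains, n_days = max(chains$first_day + chains$length - 1)) {
  cnt <- matrix(0L, n_days, n_days,
                dimnames = list(paste0("cohort", seq_len(n_days)),
                                paste0("day", seq_len(n_days))))
  for (i in seq_len(nrow(chains))) {
    c0 <- chains$first_day[i]
    dd <- c0:min(n_days, c0 + chains$length[i] - 1)
    cnt[c0, dd] <- cnt[c0, dd] + 1L
  }
  cnt
}

#' Classify cells as transient or sustained
#'
#' Two conventions are exposed: for population counts, transient = chain
#' length <= 2 days and sustained = > 2 days; for per-cell property
#' analyses, transient = exactly 1 day, sustained = > 2 days, and 2-day
#' cells are excluded (`NA`) to minimize classification error.
#'
#' @param chains output of [build_consistency_chains()].
#' @param convention `"counts"` or `"properties"`.
#' @return factor with levels `transient`, `sustained` (NA = excluded).
#' @export
classify_cells <- function(chains, convention = c("counts", "properties")) {
  convention <- match.arg(convention)
  len <- chains$length
  lab <- ifelse(len > 2, "sustained",
                if (convention == "counts") "transient"
                else NA_character_)
  if (convention == "properties") lab[len == 1] <- "transient"
  factor(lab, levels = c("transient", "sustained"))
}

#' Double-exponential decay fit
#'
#' Least-squares fit of `N(d) = Amp1 exp(-(d - d0)/tau_fast) +
#' Amp2 exp(-(d - d0)/tau_slow)` to per-day counts, with the time constants
#' ordered so `tau_fast < tau_slow`. Falls back to a single exponential
#' (flagged) if the two-component fit does not converge.
#'
#' @param counts survivor counts per day.
#' @param day day axis (defaults to `1:length(counts)`).
#' @param d0 time origin (defaults to `day[1]`).
#' @return object of class `decay_fit`: list with `Amp1`, `Amp2`,
#'   `tau_fast`, `tau_slow`, `residuals`, `fitted`, `converged`,
#'   `single_exponential`.
#' @export
fit_double_exponential <- function(counts, day = seq_along(counts), d0 = day[1]) {
  stopifnot(length(counts) == length(day), length(counts) >= 3)
  df <- data.frame(t = day - d0, y = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-t / tf) + a2 * exp(-t / ts), data = df,
                      start = list(a1 = max(counts) * 0.7,
                                   a2 = max(counts) * 0.3,
                                   tf = 0.5, ts = 5),
                      lower = c(0, 0, 1e-3, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  single <- FALSE
  if (is.null(fit)) {
    warning("double-exponential fit failed; using single-exponential fallback")
    fit <- minpack.lm::nlsLM(y ~ a1 * exp(-t / tf), data = df,
                             start = list(a1 = max(counts), tf = 1),
                             lower = c(0, 1e-3))
    co <- coef(fit)
    res <- structure(list(Amp1 = unname(co["a1"]), Amp2 = 0,
                          tau_fast = unname(co["tf"]), tau_slow = Inf,
                          residuals = stats::residuals(fit),
                          fitted = stats::fitted(fit),
                          converged = FALSE, single_exponential = TRUE),
                     class = "decay_fit")
    return(res)
  }
  co <- coef(fit)
  taus <- c(co["tf"], co["ts"]); amps <- c(co["a1"], co["a2"])
  o <- order(taus)
  structure(list(Amp1 = unname(amps[o][1]), Amp2 = unname(amps[o][2]),
                 tau_fast = unname(taus[o][1]), tau_slow = unname(taus[o][2]),
                 residuals = stats::residuals(fit), fitted = stats::fitted(fit),
                 converged = TRUE, single_exponential = FALSE),
            class = "decay_fit")
}

#' Expected past place cells under a memoryless random process
#'
#' Evaluates the closed-form expectation of the number of "past" place
#' cells per day if place-cell identity were redrawn independently every
#' day: each cell is a place cell with probability `p_pc` at a uniform
#' location, and a cell counts as a past place cell on day d if it has been
#' a place cell on every day since some earlier start day c, with every
#' location within the jitter window of the day-c location (probability
#' `jitter_fraction` per day). Each (start day, current day) chain
#' contributes `A_c * p_pc^k * jitter_fraction^(k-1)` with `k = d - c + 1`.
#'
#' @param n_total available neuron population (A on day 1).
#' @param p_pc per-day probability that a neuron is a place cell.
#' @param jitter_fraction probability that a redrawn location falls within
#'   the consistency window (60 cm / 180 cm ~ 0.33).
#' @param n_days number of experimental days.
#' @param decrement `"none"` keeps the available population fixed (a truly
#'   memoryless process); `"accumulated"` shrinks it each day by the
#'   accumulated expected past count.
#' @return list with `per_day` (expected past count, day 1..n_days) and
#'   `total` (sum over days 2..n_days).
#' @export
expected_random_past_pcs <- function(n_total = 2511, p_pc = 0.3,
                                     jitter_fraction = 0.33, n_days = 7,
                                     decrement = c("none", "accumulated")) {
  stopifnot(p_pc >= 0, p_pc <= 1, jitter_fraction >= 0, jitter_fraction <= 1,
            n_days >= 1)
  decrement <- match.arg(decrement)
  A <- numeric(n_days); A[1] <- n_total
  past <- numeric(n_days)
  for (d in seq_len(n_days)[-1]) {
    k <- 2:d
    past[d] <- sum(A[d - k + 1] * p_pc^k * jitter_fraction^(k - 1))
    A[d] <- if (decrement == "accumulated") A[d - 1] - past[d] else n_total
  }
  list(per_day = past, total = sum(past[-1]))
}

#' Monte-Carlo oracle for the memoryless past-place-cell expectation
#'
#' Simulates the memoryless process directly: every day each of `n_total`
#' cells independently becomes a place cell with probability `p_pc` at a
#' uniform belt location; for each day d the simulation counts the chains
#' (start day c < d, all days c..d active, all locations within `window`
#' cm of the day-c location) -- the same quantity the closed form
#' [expected_random_past_pcs()] computes with `decrement = "none"`.
#'
#' @inheritParams expected_random_past_pcs
#' @param window consistency window in cm.
#' @param track_length belt length in cm.
#' @param n_reps number of Monte-Carlo replicates.
#' @return list with `per_day` (mean past chain count per day), `total`
#'   (mean of the day 2..n_days sum) and `se_total` (standard error).
#' @export
simulate_random_past_pcs <- function(n_total = 2511, p_pc = 0.3, n_days = 7,
                                     window = 30, track_length = 180,
                                     n_reps = 100) {
  per_day <- matrix(0, n_reps, n_days)
  for (r in seq_len(n_reps)) {
    active <- matrix(stats::runif(n_total * n_days) < p_pc, n_total, n_days)
    loc <- matrix(stats::runif(n_total * n_days, 0, track_length),
                  n_total, n_days)
    for (c0 in seq_len(n_days - 1)) {
      alive <- active[, c0]
      for (d in (c0 + 1):n_days) {
        alive <- alive & active[, d] &
          circ_dist(loc[, d], loc[, c0], track_length) <= window
        per_day[r, d] <- per_day[r, d] + sum(alive)
      }
    }
  }
  tot <- rowSums(per_day[, -1, drop = FALSE])
  list(per_day = colMeans(per_day), total = mean(tot),
       se_total = stats::sd(tot) / sqrt(n_reps))
}

#' Past and new place-cell counts per day
#'
#' A day-d place cell is "past" if it held a field within `window` cm
#' (circular) of its day-d location on any earlier day, else "new".
#'
#' @inheritParams build_consistency_chains
#' @return data.frame per (mouse, condition, day): past, new, total and the
#'   past/new ratio. `past + new = total` by construction.
#' @export
count_past_new <- function(pf, window = 30, track_length = 180) {
  key <- interaction(pf$mouse, pf$condition, drop = TRUE)
  out <- lapply(split(seq_len(nrow(pf)), key), function(ix) {
    days <- sort(unique(pf$day[ix]))
    res <- lapply(days, function(d) {
      now <- ix[pf$day[ix] == d]
      before <- ix[pf$day[ix] < d]
      is_past <- vapply(now, function(i) {
        prev <- before[pf$cell[before] == pf$cell[i]]
        length(prev) > 0 &&
          any(circ_dist(pf$pf_location_cm[prev], pf$pf_location_cm[i],
                        track_length) <= window)
      }, logical(1))
      data.frame(mouse = pf$mouse[now[1]], condition = pf$condition[now[1]],
                 day = d, past = sum(is_past), new = sum(!is_past),
                 total = length(now),
                 ratio = sum(is_past) / max(sum(!is_past), 1))
    })
    do.call(rbind, res)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-mouse place-field stability index
#'
#' Fractional excess of low-shift place cells over a bootstrap random
#' expectation, for a 2-day interval (day d versus day d+2): cells with a
#' field on both days and |shift| < `shift_max` are counted; the null
#' counts come from `n_boot` permutations of the day-(d+2) locations across
#' cells; the index is (observed - upper 99% CI of the null) / total place
#' cells on day d.
#'
#' @inheritParams build_consistency_chains
#' @param day first day of the 2-day interval.
#' @param shift_max low-shift bound in cm (first three 5-cm bins).
#' @param n_boot number of permutation resamples.
#' @param conf upper confidence level of the null.
#' @return data.frame per (mouse, condition): observed, null_ci, total,
#'   index, flagged (TRUE if fewer than 10 paired cells).
#' @export
stability_index <- function(pf, day, shift_max = 20, n_boot = 10000,
                            conf = 0.99, track_length = 180) {
  key <- interaction(pf$mouse, pf$condition, drop = TRUE)
  out <- lapply(split(seq_len(nrow(pf)), key), function(ix) {
    a <- ix[pf$day[ix] == day]
    b <- ix[pf$day[ix] == day + 2]
    common <- intersect(pf$cell[a], pf$cell[b])
    la <- pf$pf_location_cm[a][match(common, pf$cell[a])]
    lb <- pf$pf_location_cm[b][match(common, pf$cell[b])]
    total <- length(a)
    flagged <- length(common) < 10
    obs <- sum(circ_dist(la, lb, track_length) < shift_max)
    null_counts <- if (length(common) >= 2)
      vapply(seq_len(n_boot), function(i)
        sum(circ_dist(la, sample(lb), track_length) < shift_max), numeric(1))
    else rep(NA_real_, n_boot)
    ci <- stats::quantile(null_counts, conf, names = FALSE, na.rm = TRUE)
    data.frame(mouse = pf$mouse[ix[1]], condition = pf$condition[ix[1]],
               day = day, observed = obs, null_ci = ci, total = total,
               index = if (total > 0) (obs - ci) / total else NA_real_,
               flagged = flagged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
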
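## Trial-by-trial cosine similarity, discrimination indices, field-density
## bootstrap, onset-lap distributions, day-to-day correlation and licking
## selectivity.

#' Trial-by-trial cosine similarity matrix
#'
#' Every lap's binned activity vector is divided by its l2 norm and the
#' similarity matrix is the product of the normalized matrix with its
#' transpose. For a population matrix, the per-cell lap x bin maps are
#' concatenated horizontally (same laps, stacked bins) before normalizing.
#' Laps with zero norm give zero similarity to every lap.
#'
#' @param maps a lap x bin matrix (single cell) or a list of such matrices
#'   with identical lap sets (population).
#' @param lap_condition optional per-lap condition labels, attached to the
#'   result.
#' @return lap x lap similarity matrix of class `similarity_matrix` with
#'   attributes `lap_condition` and `zero_rows`.
#' @export
similarity_matrix <- function(maps, lap_condition = NULL) {
  A <- if (is.list(maps)) do.call(cbind, maps) else maps
  stopifnot(nrow(A) >= 2)
  A[is.na(A)] <- 0
  nrm <- sqrt(rowSums(A^2))
  zero <- nrm == 0
  An <- A / ifelse(zero, 1, nrm)
  C <- An %*% t(An)
  attr(C, "lap_condition") <- lap_condition
  attr(C, "zero_rows") <- zero
  class(C) <- c("similarity_matrix", class(C))
  C
}

#' Context discrimination index (CDI / PDI)
#'
#' For each lap (row of the similarity matrix), the mean similarity to the
#' other laps of the same reward condition minus the mean similarity to
#' laps of the alternate condition; the index is the average over laps.
#' Applied to a single-cell similarity matrix this is the cellular
#' discrimination index (CDI); applied to a population matrix, the
#' population discrimination index (PDI). Self-similarity (the diagonal)
#' and zero-activity laps are excluded from the averages.
#'
#' @param C a `similarity_matrix`.
#' @param lap_condition per-lap labels; defaults to the attribute on `C`.
#' @return scalar in `[-1, 1]`; `NA` (flagged with a warning) if either
#'   condition has fewer than 2 usable laps.
#' @export
discrimination_index <- function(C, lap_condition = attr(C, "lap_condition")) {
  stopifnot(!is.null(lap_condition), length(lap_condition) == nrow(C))
  zero <- attr(C, "zero_rows") %||% rep(FALSE, nrow(C))
  use <- which(!zero)
  cond <- as.character(lap_condition)
  if (length(unique(cond[use])) < 2 || min(table(cond[use])) < 2) {
    warning("need at least 2 usable laps per condition for a discrimination index")
    return(NA_real_)
  }
  per_row <- vapply(use, function(i) {
    same <- setdiff(use[cond[use] == cond[i]], i)
    diff <- use[cond[use] != cond[i]]
    mean(C[i, same]) - mean(C[i, diff])
  }, numeric(1))
  mean(per_row)
}

#' Place-field spatial density with bootstrap confidence band
#'
#' Field count per cm of belt per spatial bin, with a pointwise confidence
#' band obtained by redrawing the same number of locations uniformly
#' `n_boot` times. Bins whose density exceeds the upper band are
#' over-represented.
#'
#' @param locations field locations in cm.
#' @param n_bins,track_length spatial discretization.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level of the band (two-sided).
#' @return data.frame per bin: bin_center_cm, count, density_per_cm,
#'   ci_low, ci_high, over_represented.
#' @export
pf_density <- function(locations, n_bins = 50, track_length = 180,
                       n_boot = 10000, conf = 0.99) {
  stopifnot(length(locations) >= 10)
  bw <- track_length / n_bins
  cnt <- tabulate(position_to_bin(locations, n_bins, track_length), n_bins)
  boot <- matrix(0L, n_boot, n_bins)
  n <- length(locations)
  for (b in seq_len(n_boot))
    boot[b, ] <- tabulate(position_to_bin(stats::runif(n, 0, track_length),
                                          n_bins, track_length), n_bins)
  lo <- apply(boot, 2, stats::quantile, probs = (1 - conf) / 2) / bw
  hi <- apply(boot, 2, stats::quantile, probs = 1 - (1 - conf) / 2) / bw
  data.frame(bin_center_cm = bin_centers(n_bins, track_length),
             count = cnt, density_per_cm = cnt / bw,
             ci_low = lo, ci_high = hi,
             over_represented = cnt / bw > hi)
}

#' Onset-lap distributions of sustained versus transient cells
#'
#' Empirical cumulative distributions of place-field onset laps for the two
#' stability classes, with a two-sample Kolmogorov-Smirnov comparison.
#'
#' @param onsets_sustained,onsets_transient onset laps per class.
#' @return list with `cdf_sustained`, `cdf_transient` (functions),
#'   `ks_statistic`, `p_value`.
#' @export
onset_lap_distributions <- function(onsets_sustained, onsets_transient) {
  stopifnot(length(onsets_sustained) > 0, length(onsets_transient) > 0)
  ks <- suppressWarnings(
    stats::ks.test(onsets_sustained, onsets_transient, exact = FALSE))
  list(cdf_sustained = stats::ecdf(onsets_sustained),
       cdf_transient = stats::ecdf(onsets_transient),
       ks_statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Day-to-day correlation of the place-cell representation
#'
#' Pearson correlation of the concatenated condition-averaged spatial
#' vectors of the cells present on both days.
#'
#' @param maps_a,maps_b `spatial_map` objects for the two days (same cell
#'   indexing).
#' @param cells indices of the cells to compare (e.g. place cells present
#'   on both days).
#' @return scalar correlation; `NA` with a warning if fewer than 10 cells.
#' @export
day_to_day_correlation <- function(maps_a, maps_b, cells) {
  if (length(cells) < 10) {
    warning("fewer than 10 common cells; correlation not reported")
    return(NA_real_)
  }
  vec <- function(sp) {
    conds <- sort(unique(as.character(sp$lap_condition)))
    unlist(lapply(cells, function(ci) {
      unlist(lapply(conds, function(cd) {
        m <- sp$maps[ci, sp$lap_condition == cd, , drop = FALSE]
        v <- apply(m, 3, mean, na.rm = TRUE)
        v[is.nan(v)] <- 0
        v
      }))
    }))
  }
  stats::cor(vec(maps_a), vec(maps_b))
}

#' Licking selectivity of a session
#'
#' The lick probability of a spatial bin is the fraction of laps with at
#' least one lick inside that bin. Selectivity compares the anticipatory
#' reward zone (the three bins before the reward location of the lap's
#' condition) with a random zone (three bins around the light cue,
#' non-overlapping with either reward zone):
#' `(P_ant - P_rand) / P_ant`, computed per condition and averaged.
#'
#' @param lick_map laps x bins logical (or 0/1) matrix: any lick in bin.
#' @param lap_condition per-lap condition labels.
#' @param reward_bins named vector: reward bin (1-based, first bin after
#'   reward release) per condition.
#' @param random_zone_bins integer vector of bins forming the random zone.
#' @return list with `selectivity` (session scalar; `NA` if anticipatory
#'   licking is absent), and per-condition components.
#' @export
licking_selectivity <- function(lick_map, lap_condition, reward_bins,
                                random_zone_bins) {
  n_bins <- ncol(lick_map)
  per_cond <- lapply(unique(as.character(lap_condition)), function(cd) {
    laps <- which(lap_condition == cd)
    rb <- reward_bins[[cd]]
    ant <- ((rb - 4:2) %% n_bins) + 1    # three bins before the reward bin
    m <- lick_map[laps, , drop = FALSE] > 0
    p_ant <- mean(apply(m[, ant, drop = FALSE], 1, any))
    p_rand <- mean(apply(m[, random_zone_bins, drop = FALSE], 1, any))
    sel <- if (p_ant == 0) NA_real_ else (p_ant - p_rand) / p_ant
    data.frame(condition = cd, p_anticipatory = p_ant, p_random = p_rand,
               selectivity = sel)
  })
  per_cond <- do.call(rbind, per_cond)
  if (all(is.na(per_cond$selectivity)))
    warning("no anticipatory licking; selectivity undefined")
  list(selectivity = mean(per_cond$selectivity, na.rm = TRUE),
       per_condition = per_cond)
}
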
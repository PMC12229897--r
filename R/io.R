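## Session container IO and the end-to-end pipeline driver. Sessions are
## stored as a plain-text directory: meta.json (scalar attributes and the
## per-lap condition labels) plus CSV arrays, with an explicit schema
## version for validation.

.session_schema_version <- "1.0"
.session_fields <- c("traces", "position", "velocity", "licks", "lap",
                     "lap_condition", "reward_cm", "frame_rate",
                     "track_length", "mouse", "day")

#' Write a session recording
#'
#' @param session a `session_recording` (see [generate_experiment()]).
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = .session_schema_version,
               mouse = session$mouse, day = session$day,
               frame_rate = session$frame_rate,
               track_length = session$track_length,
               cue_cm = session$cue_cm,
               reward_cm = as.list(session$reward_cm),
               lap_condition = session$lap_condition,
               n_cells = nrow(session$traces),
               n_frames = ncol(session$traces))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(position = session$position,
                              velocity = session$velocity,
                              licks = session$licks, lap = session$lap),
                   file.path(path, "behavior.csv"), row.names = FALSE)
  utils::write.table(session$traces, file.path(path, "traces.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a session recording
#'
#' Validates the schema version and stream alignment; errors name the
#' missing or inconsistent field.
#'
#' @param path directory written by [write_session()].
#' @return a `session_recording`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("missing session file: meta.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("schema_version", "mouse", "day", "frame_rate",
              "track_length", "reward_cm", "lap_condition", "n_frames"))
    if (is.null(meta[[f]])) stop("session metadata missing field: ", f)
  if (meta$schema_version != .session_schema_version)
    stop("unknown session schema version: ", meta$schema_version)
  bf <- file.path(path, "behavior.csv")
  tf <- file.path(path, "traces.csv")
  if (!file.exists(bf)) stop("missing session file: behavior.csv")
  if (!file.exists(tf)) stop("missing session file: traces.csv")
  beh <- utils::read.csv(bf)
  for (f in c("position", "velocity", "licks", "lap"))
    if (is.null(beh[[f]])) stop("behavior table missing field: ", f)
  traces <- as.matrix(utils::read.table(tf, sep = ","))
  dimnames(traces) <- NULL
  if (meta$n_cells == 0) traces <- matrix(numeric(0), 0, meta$n_frames)
  if (ncol(traces) != nrow(beh))
    stop("length mismatch: traces have ", ncol(traces),
         " frames but behavior has ", nrow(beh))
  if (max(beh$lap) != length(meta$lap_condition))
    stop("length mismatch: lap stream and lap_condition disagree")
  structure(list(traces = traces, position = beh$position,
                 velocity = beh$velocity, licks = beh$licks, lap = beh$lap,
                 lap_condition = meta$lap_condition,
                 reward_cm = unlist(meta$reward_cm),
                 cue_cm = meta$cue_cm %||% NA_real_,
                 frame_rate = meta$frame_rate,
                 track_length = meta$track_length,
                 mouse = meta$mouse, day = meta$day,
                 schema_version = meta$schema_version),
            class = "session_recording")
}

#' Process a session into a transient-masked spatial map
#'
#' Runs the signal stage: dF/F conversion, baseline-noise estimation,
#' significant-transient masking, and lap x bin map construction.
#'
#' @param session a `session_recording`.
#' @param threshold_sd transient peak threshold in noise s.d.
#' @param velocity_threshold minimum speed (cm/s) for map frames.
#' @param n_bins spatial bins.
#' @return a `spatial_map` with attribute `noise_sd` (per cell).
#' @export
process_session <- function(session, threshold_sd = 3,
                            velocity_threshold = 2, n_bins = 50) {
  nc <- nrow(session$traces)
  masked <- matrix(0, nc, ncol(session$traces))
  noise <- numeric(nc)
  for (ci in seq_len(nc)) {
    d <- compute_dff(session$traces[ci, ], session$frame_rate)
    noise[ci] <- estimate_baseline_noise(d)
    m <- detect_significant_transients(d, noise[ci],
                                       threshold_sd = threshold_sd)
    masked[ci, ] <- ifelse(m, d$values, 0)
  }
  sp <- compute_spatial_map(masked, session$position, session$velocity,
                            session$lap, session$lap_condition,
                            n_bins = n_bins,
                            track_length = session$track_length,
                            velocity_threshold = velocity_threshold)
  attr(sp, "noise_sd") <- noise
  sp
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the sessions, runs signal processing and
#' place-field detection per session, then the cross-day stability and
#' per-session metrics stages, and writes the result tables as CSV.
#'
#' @param config a `generator_config`, or a path to a YAML file whose
#'   fields override [generator_config()] defaults.
#' @param out_dir output directory for the CSV tables (created).
#' @param n_shuffles shuffle count for place-field criterion 1.
#' @param window consistency window in cm.
#' @param sessions optional pre-built list of `session_recording`s
#'   (bypasses the generator).
#' @return invisible list with the place-field table, chains, cohort
#'   counts, past/new counts and per-session metrics.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = NULL,
                         n_shuffles = 300, window = 30, sessions = NULL) {
  if (is.character(config)) {
    ov <- yaml::read_yaml(config)
    config <- do.call(generator_config, ov)
  }
  set.seed((config$seed + 997) %% .Machine$integer.max)  # shuffle-test stream
  truth <- NULL
  if (is.null(sessions)) {
    exp <- generate_experiment(config)
    sessions <- exp$sessions
    truth <- exp$truth
  }
  pf_list <- list(); metrics_list <- list()
  for (ses in sessions) {
    sp <- process_session(ses)
    pf <- detect_place_fields(sp, mouse = ses$mouse, day = ses$day,
                              n_shuffles = n_shuffles)
    pf_list[[length(pf_list) + 1]] <- pf
    ## per-session metrics: PDI over detected place cells, licking
    pdi <- NA_real_
    if (nrow(pf) >= 1) {
      cells <- sort(unique(pf$cell))
      mats <- lapply(cells, function(ci) {
        m <- sp$maps[ci, , , drop = TRUE]
        m[is.na(m)] <- 0
        m
      })
      C <- similarity_matrix(mats, lap_condition = sp$lap_condition)
      pdi <- suppressWarnings(discrimination_index(C))
    }
    lick_map <- lick_lap_map(ses)
    rb <- vapply(ses$reward_cm, position_to_bin,
                 numeric(1), n_bins = dim(sp$maps)[3],
                 track_length = ses$track_length)
    rand_zone <- random_zone_bins(ses, n_bins = dim(sp$maps)[3])
    sel <- suppressWarnings(
      licking_selectivity(lick_map, ses$lap_condition, rb, rand_zone))
    metrics_list[[length(metrics_list) + 1]] <-
      data.frame(mouse = ses$mouse, day = ses$day, pdi = pdi,
                 licking_selectivity = sel$selectivity,
                 n_place_fields = nrow(pf))
  }
  pf_all <- do.call(rbind, pf_list)
  metrics <- do.call(rbind, metrics_list)
  chains <- if (nrow(pf_all)) build_consistency_chains(pf_all, window) else NULL
  cohorts <- if (!is.null(chains)) cohort_counts(chains, config$n_days) else NULL
  pastnew <- if (nrow(pf_all)) count_past_new(pf_all, window) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pf_all, file.path(out_dir, "place_fields.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(chains))
      utils::write.csv(chains, file.path(out_dir, "chains.csv"),
                       row.names = FALSE)
    if (!is.null(cohorts))
      utils::write.csv(as.data.frame(cohorts),
                       file.path(out_dir, "cohort_counts.csv"))
    if (!is.null(pastnew))
      utils::write.csv(pastnew, file.path(out_dir, "past_new.csv"),
                       row.names = FALSE)
    if (!is.null(truth))
      utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    manifest <- list(seed = config$seed, n_cells = config$n_cells,
                     n_days = config$n_days, window = window,
                     n_shuffles = n_shuffles,
                     package_version = as.character(
                       utils::packageVersion("pfdyn")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(place_fields = pf_all, metrics = metrics, chains = chains,
                 cohort_counts = cohorts, past_new = pastnew, truth = truth))
}

#' Lap x bin lick indicator map of a session
#'
#' @param session a `session_recording`.
#' @param n_bins spatial bins.
#' @return laps x bins 0/1 matrix: any lick in the bin on that lap.
#' @export
lick_lap_map <- function(session, n_bins = 50) {
  n_laps <- max(session$lap)
  bin <- position_to_bin(session$position, n_bins, session$track_length)
  m <- matrix(0L, n_laps, n_bins)
  hit <- session$licks > 0
  if (any(hit)) {
    idx <- unique(cbind(session$lap[hit], bin[hit]))
    m[idx] <- 1L
  }
  m
}

#' Random-zone bins around the light cue
#'
#' Three bins centred on the cue location, excluding any bin inside either
#' reward anticipatory zone.
#'
#' @param session a `session_recording`.
#' @param n_bins spatial bins.
#' @return integer vector of bin indices.
#' @export
random_zone_bins <- function(session, n_bins = 50) {
  cue_bin <- position_to_bin(session$cue_cm, n_bins, session$track_length)
  cand <- ((cue_bin - 1 + -1:1) %% n_bins) + 1
  rz <- vapply(session$reward_cm, position_to_bin, numeric(1),
               n_bins = n_bins, track_length = session$track_length)
  excl <- unique(unlist(lapply(rz, function(rb) ((rb - 2:4) %% n_bins) + 1)))
  setdiff(cand, excl)
}
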
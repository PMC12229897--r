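# Small in-code fixtures shared across test files.

# lap x bin map with a Gaussian field at `centre_cm` on the given laps
field_map <- function(n_laps = 20, n_bins = 50, centre_cm = 90,
                      laps = seq_len(n_laps), amplitude = 1, width_cm = 30,
                      track_length = 180) {
  sg <- width_cm / (2 * sqrt(2 * log(2)))
  ctr <- bin_centers(n_bins, track_length)
  m <- matrix(0, n_laps, n_bins)
  for (l in laps)
    m[l, ] <- amplitude * exp(-circ_dist(ctr, centre_cm, track_length)^2 /
                                (2 * sg^2))
  m
}

# minimal place-field table row builder
pf_row <- function(mouse = 1, day, cell, loc, condition = "RL1") {
  data.frame(mouse = mouse, day = day, condition = condition, cell = cell,
             pf_location_cm = loc)
}

# small noise-free generator configuration used by several suites
small_config <- function(...) {
  generator_config(n_cells = 30, n_days = 2, laps_per_session = 30,
                   noise_sd = 0, seed = 11, ...)
}
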
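#!/usr/bin/env Rscript

# Stage 4: discrimination and behavior metrics. Per-cell CDI and population
# PDI from trial-by-trial cosine similarity, field-density bootstrap bands,
# onset-lap distributions of the stability classes, day-to-day map
# correlation and licking selectivity.

library(pfdyn)

cfg <- do.call(generator_config, yaml::read_yaml("results/generator_config.yaml"))
pf <- read.csv("results/place_fields.csv")
chains <- read.csv("results/chains.csv")
set.seed(4)

metrics <- NULL
sps <- list()
for (d in seq_len(cfg$n_days)) {
  ses <- read_session(sprintf("results/sessions/m1_d%d", d))
  sp <- suppressWarnings(process_session(ses))
  sps[[d]] <- sp
  cells <- sort(unique(pf$cell[pf$day == d]))
  pdi <- cdi <- NA_real_
  if (length(cells) >= 2) {
    mats <- lapply(cells, function(ci) {
      m <- sp$maps[ci, , , drop = TRUE]; m[is.na(m)] <- 0; m
    })
    pdi <- suppressWarnings(discrimination_index(
      similarity_matrix(mats, lap_condition = sp$lap_condition)))
    cdi <- mean(vapply(mats, function(m) suppressWarnings(
      discrimination_index(similarity_matrix(m, sp$lap_condition))),
      numeric(1)), na.rm = TRUE)
  }
  rb <- vapply(ses$reward_cm, function(x) floor(x / 3.6) + 1, numeric(1))
  sel <- suppressWarnings(licking_selectivity(
    lick_lap_map(ses), ses$lap_condition, rb, random_zone_bins(ses)))
  metrics <- rbind(metrics, data.frame(
    day = d, pdi = pdi, mean_cdi = cdi,
    licking_selectivity = sel$selectivity))
}
write.csv(metrics, "results/metrics.csv", row.names = FALSE)
print(metrics, digits = 3)

## density of sustained vs transient fields
sus_cells <- chains$cell[chains$class_counts == "sustained"]
dens_s <- pf_density(pf$pf_location_cm[pf$cell %in% sus_cells], n_boot = 2000)
write.csv(dens_s, "results/density_sustained.csv", row.names = FALSE)
cat("over-represented bins (sustained):", sum(dens_s$over_represented), "\n")

## onset-lap distributions by class
key <- paste(pf$condition, pf$cell)
ckey <- paste(chains$condition, chains$cell)
cls <- chains$class_counts[match(key, ckey)]
ons <- onset_lap_distributions(pf$onset_lap[cls == "sustained"],
                               pf$onset_lap[cls == "transient"])
cat(sprintf("onset-lap KS statistic sustained vs transient: %.3f (p = %.3g)\n",
            ons$ks_statistic, ons$p_value))

## day-to-day correlation of the representation
for (d in 1:(cfg$n_days - 1)) {
  both <- intersect(pf$cell[pf$day == d], pf$cell[pf$day == d + 1])
  r <- suppressWarnings(day_to_day_correlation(sps[[d]], sps[[d + 1]], both))
  cat(sprintf("day %d-%d correlation (n = %d cells): %.3f\n",
              d, d + 1, length(both), r))
}
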
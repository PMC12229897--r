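#!/usr/bin/env Rscript

# Stage 1: generate the synthetic 7-day experiment used by the downstream
# analysis stages. The design mirrors the study conditions (two alternating
# reward locations in 12-18-lap blocks, transient/sustained subpopulations,
# BTSP-like induction) at a desk-friendly scale: 150 cells and 60 laps per
# session instead of 2,511 cells and ~126 laps.

library(pfdyn)

cfg <- generator_config(n_cells = 150, n_days = 7, laps_per_session = 60,
                        noise_sd = 0.05, seed = 20260926)
exp1 <- generate_experiment(cfg)

dir.create("results/sessions", showWarnings = FALSE, recursive = TRUE)
for (ses in exp1$sessions)
  write_session(ses, sprintf("results/sessions/m%d_d%d", ses$mouse, ses$day))
write.csv(exp1$truth, "results/ground_truth.csv", row.names = FALSE)
yaml::write_yaml(list(n_cells = cfg$n_cells, n_days = cfg$n_days,
                      laps_per_session = cfg$laps_per_session,
                      noise_sd = cfg$noise_sd, seed = cfg$seed),
                 "results/generator_config.yaml")

cat(sprintf("generated %d sessions, %d ground-truth fields (%d sustained, %d transient)\n",
            length(exp1$sessions), nrow(exp1$truth),
            sum(exp1$truth$class == "sustained"),
            sum(exp1$truth$class == "transient")))
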
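# pfdyn — longitudinal place-field dynamics, stability and plasticity

`pfdyn` is an R package plus analysis workflow for week-long two-photon
calcium-imaging experiments in hippocampal CA1, where the same population
of neurons is recorded daily while a mouse runs a cued linear treadmill
with two alternating reward locations. It is aimed at systems
neuroscientists who want a tested, end-to-end reimplementation of this
kind of analysis and of the state models used to interpret it.

The package covers:

- **Signal**: ΔF/F with a 50th-percentile 25-s moving baseline,
  below-mode baseline-noise estimation, 3-s.d. significant-transient
  masking, and lap × bin spatial activity maps (50 × 3.6-cm bins,
  speed > 2 cm/s).
- **Place fields**: Skaggs spatial information with a per-lap circular
  rotation shuffle test, a 54-cm peak gate, 3-of-5-lap onset detection and
  a 40% reliability criterion, applied per 12–18-lap behavioral epoch.
- **Stability**: signed circular day-to-day shifts and their Gaussian fit,
  ±30-cm consistency chains, transient/sustained classification,
  double-exponential cohort decay N(d) = Amp₁e^(−d/τ_fast) + Amp₂e^(−d/τ_slow),
  past/new accounting, the memoryless-random expectation
  A·0.3^d·0.33^(d−1) with a Monte-Carlo oracle, and a bootstrap stability
  index.
- **Metrics**: trial-by-trial cosine similarity and cellular/population
  context-discrimination indices (CDI/PDI), field-density bootstrap bands,
  onset-lap CDFs with KS comparison, day-to-day map correlation, licking
  selectivity.
- **BTSP**: detection of behavioral-timescale-synaptic-plasticity
  induction events (top-20th-percentile amplitude ≥ 1 ΔF/F, 45-cm gate,
  3-of-5 subsequent laps, backward COM shift), plateau thresholds and
  rates, the field-width ~ induction-speed regression, and plateau
  detection in membrane-potential traces (spike removal at dV/dt = 25 V/s,
  −35 mV threshold, <150-ms merge rule).
- **Models**: the three-pool kinetic model, the cascade-type state model
  with salience and history weighting, and the progressive-stabilization
  alternative.
- **Synthetic data**: a generator that emulates the study design (2,511
  cells × 7 days, ~126 laps in alternating blocks, BTSP-like induction
  with width = 0.80·v + 18.95 cm, backward drift, transient/sustained
  subpopulations) with full ground truth, so every stage is testable.

## Worked example

Generate a small noise-free experiment, detect fields, and check them
against ground truth:

```r
library(pfdyn)
cfg <- generator_config(n_cells = 60, n_days = 3, laps_per_session = 32,
                        noise_sd = 0, seed = 12)
exp1 <- generate_experiment(cfg)
pf <- do.call(rbind, lapply(exp1$sessions, function(ses) {
  sp <- process_session(ses)         # dF/F -> transients -> lap x bin maps
  detect_place_fields(sp, mouse = ses$mouse, day = ses$day, n_shuffles = 200)
}))
m <- merge(exp1$truth, pf, by = c("mouse", "day", "condition", "cell"))
mean(abs(circ_diff(m$centre_cm, m$pf_location_cm)) <= 3.6)  # 1 (all within one bin)

chains <- build_consistency_chains(pf, window = 30)
table(classify_cells(chains, "counts"))
```

Model-side quantities, computed at study scale:

```r
expected_random_past_pcs(2511, 0.3, 0.33, 7)$total
#> 487.53          # expected past place cells, days 2-7, memoryless process

sim <- three_pool_simulate(three_pool_config())
fit_double_exponential(sim$cohort_day1, day = 1:7)[c("tau_fast", "tau_slow")]
#> $tau_fast  0.6698   $tau_slow  4.5998   # self-consistent with the 0.67/4.6-d fit

set.seed(1)
mean(cascade_simulate(cascade_config(), n_reps = 50)$daily_counts)
#> ~767             # mean daily active place cells, cascade model
```

The first number is the expected count of place cells that reappear
within ±30 cm of an earlier field if identity were redrawn at random
every day — far below observed counts, which is the case for genuine
day-to-day memory. The τ values show the three-pool model reproduces the
double-exponential cohort decay it was configured from, and the cascade
model's printed coefficients yield the observed ~767 active place cells
per day per reward condition.

## Analysis workflow

`analysis/01_simulate.R` … `06_models.R` are thin numbered drivers that
run the stages in order on a desk-scale synthetic experiment (150 cells,
7 days, 60 laps) and write their tables under `results/`: sessions and
ground truth, `place_fields.csv`, `chains.csv`/`cohort_counts.csv`/
`past_new.csv`/`stability_index.csv`, `metrics.csv` and density/onset
outputs, `btsp_events.csv`/`plateau_rates.csv`/`vm_plateaus.csv`, and
`model_counts.csv`. Each script prints what it found; run them from the
repository root with `Rscript analysis/01_simulate.R`, etc.

## Layout

- `R/` — package code: generator, signal, placefields, stability, metrics,
  btsp, models, io/pipeline.
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  built in code).
- `analysis/` — the numbered workflow drivers.
- `vignettes/place-field-stability.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical decisions and known
  limitations.
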
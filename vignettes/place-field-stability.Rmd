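---
title: "Place-field stability analysis and stabilization models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Place-field stability analysis and stabilization models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Hippocampal CA1 place cells (PCs) fire at specific belt positions (place
fields, PFs) while a head-fixed mouse runs a cued linear treadmill. When the
same neuronal population is imaged daily for a week, most cells hold a field
only briefly while a growing minority keeps a consistent field for many
days. `pfdyn` implements the full analysis chain for such experiments --
from raw fluorescence to multi-day stability statistics and
plasticity-event detection -- together with three generative models of how
a stable population could emerge, and a synthetic-data generator that
emulates the study design so that every stage can be validated against
known ground truth.

The experimental design assumed throughout: a 180-cm belt divided into 50
bins of 3.6 cm, ~30-Hz imaging, one session per day for 7 days, ~126 laps
per session grouped in 12--18-lap blocks that alternate between two
cue-contingent reward locations (conditions RL1 at 100 cm and RL2 at
160 cm, light cue at 40 cm).

# Signal processing

`compute_dff()` forms dF/F = (F - F0)/F0 with F0 the 50th percentile of a
centred 25-s moving window. The window is centred (not trailing) to avoid
phase lag, and truncated at the trace edges; the interior uses
`stats::runmed` and the edges explicit truncated medians, so the result is
identical to a naive per-frame median (tested against that oracle).

Baseline noise is the s.d. of negative-going deviations around the mode of
the dF/F histogram; because transients are positive-going, this estimate
is insensitive to sparse activity (verified on paired simulations). The
mode is located by a coarse-to-fine histogram search with an initial bin
width of one tenth of a robust scale; the bin count is capped so
near-degenerate traces cannot request absurd histograms.

A *significant transient* is a contiguous epoch above 1 noise s.d. whose
peak exceeds 3 s.d.; only frames inside such epochs count as functional
activity (the rest are zeroed before mapping). No minimum-duration
criterion is imposed. Spatial maps average masked dF/F per lap and bin
over frames with speed > 2 cm/s; unvisited bins are missing (`NA`), never
zero, so absent sampling is not mistaken for silence.

**A known interaction.** For very wide fields on highly reliable cells,
the in-field fraction of the 25-s window approaches one half and the
percentile baseline rises by several percent inside the field, which
compresses measured field widths by roughly 10% at the widest widths the
generator produces. This is a property of the percentile-baseline method
itself, reproduced faithfully here; it is why the width-velocity
regression on full-pipeline synthetic data recovers a slope of ~0.73
rather than the generating 0.80 (the regression recovers the generating
line exactly when given uncompressed widths).

# Place-field criteria

A cell has a field in a behavioral epoch (one reward-condition block) if
all four criteria hold:

1. the epoch's spatial information exceeds the 95th percentile of a null
   built by circularly rotating each lap's binned activity by an
   independent random offset (default 1,000 rotations; the observed value
   must strictly exceed the threshold);
2. laps count as field-active only if their peak dF/F lies within 54 cm
   (15 bins, measured circularly -- the belt is a loop) of the epoch-average
   peak;
3. an onset lap exists: the first active lap within the earliest sliding
   5-lap window containing at least 3 active laps;
4. the active-lap fraction strictly after the onset lap is at least 0.40.

Spatial information is the Skaggs form, `sum p_i (r_i) log2(r_i)` with
`r_i` the occupancy-normalized rate ratio; a single active bin under
uniform occupancy gives exactly `log2(50)` (closed-form test case).
A cell-condition passes if *any* epoch passes (the criteria are evaluated
per epoch); the field location is the peak of the lap-averaged activity
over all laps of the passing epochs, reported at the bin centre, with
peak ties broken toward the lowest bin index for determinism.

# Multi-day stability

Day-to-day field shifts are signed circular differences wrapped into
(-90, 90] cm, negative = backward relative to running. The population
shift distribution is fit with a Gaussian (histogram least squares); its
3-s.d. spread motivates the +/-30-cm consistency window (a +/-20-cm
window is the stricter alternative, exposed as a parameter).

A *consistency chain* starts at a cell's first day with a field and
extends over consecutive days with a field within the window of the
*first-day* location; a missed day or jump ends the chain. Chain lengths
classify cells: for population counts, transient <= 2 days and sustained
> 2 days; for per-cell property analyses, transient = 1 day, sustained
> 2, with 2-day cells excluded to minimize classification error. Cohort
survivor counts are fit with
`N(d) = Amp1 exp(-d/tau_fast) + Amp2 exp(-d/tau_slow)` by
Levenberg-Marquardt least squares with nonnegativity bounds, time
constants ordered, and a flagged single-exponential fallback.

**The memoryless-random expectation.** The expected number of "past" PCs
under a history-free process uses the recurrence `A x 0.3^d x 0.33^(d-1)`
(A = 2,511 available neurons, 0.3 the daily PC probability, 0.33 the
+/-30-cm jitter window as a fraction of the belt). The printed form is
terse, so the implementation makes the expansion explicit: for each
current day, chains of length k >= 2 that started on an earlier day
contribute `A p^k j^(k-1)`, summed over start days and over days 2--7.
Two choices were genuinely open and are exposed as parameters:

* *availability decrement*: keeping A fixed matches a truly memoryless
  process (and the Monte-Carlo oracle); decrementing A by accumulated
  past counts, as the text also suggests, lowers the total by ~8%. The
  default is no decrement.
* *jitter constant*: 0.33 as printed, versus 60/180 = 1/3 exactly.

With the printed constants and no decrement the total is 487.5 (~488);
with j = 1/3 it is 492.9. No expansion we could find gives exactly the
reported 490; the default (printed constants, no decrement) is the
closest faithful reading and agrees with the Monte-Carlo simulation of
the same process within sampling error. The Monte-Carlo oracle counts,
per day, chains (start day, current day) of within-window consecutive
activity -- the same quantity the closed form sums.

The per-mouse stability index compares, for a 2-day interval, the number
of cells with |shift| < 20 cm against the upper 99% quantile of 10,000
permutations of the later day's locations across cells (the paper says
"random distribution" without construction; permutation preserves both
marginal location distributions), normalized by the day's PC count.

# Discrimination and behavior metrics

Trial-by-trial cosine similarity normalizes each lap's binned activity
vector to unit l2 norm; the similarity matrix is the Gram matrix. For the
population version the per-cell maps are concatenated horizontally before
normalizing. The cellular/population discrimination index (CDI/PDI) is
the mean over laps of (mean within-condition similarity) minus (mean
between-condition similarity), excluding the diagonal and laps with zero
norm (dropping rather than imputing avoids 0/0). Field density per cm
gets a pointwise 99% band from 10,000 uniform redraws; onset-lap
distributions are compared with a two-sided asymptotic KS test; licking
selectivity is `(P_ant - P_rand)/P_ant` with the anticipatory zone the
three bins before the active reward location and the random zone three
bins around the light cue that overlap neither reward zone.

# BTSP and plateau detection

A calcium *event* is one lap's transient-masked activity, with amplitude
its peak dF/F (the Methods rank "all events" without defining
segmentation; one-event-per-active-lap is the simplest faithful reading
at map resolution). A putative BTSP induction must (1) have amplitude in
the cell-session top 20th percentile and >= 1 dF/F, (2--3) be followed by
at least 3 of 5 laps whose peaks lie within 45 cm of the event peak, and
(4) show a backward (negative) mean centre of mass in those laps. The COM
reference is the event lap's own COM computed with the same
activity-weighted circular estimator as the post laps, so bin
quantization cancels instead of flipping marginal signs. Field width is
the full width at half maximum of the mean post-event profile with the
half-max crossings located by linear interpolation between bin centres.

The plateau proxy threshold is the minimum amplitude of the session's
detected BTSP events; every event at or above it counts as a putative
plateau. On synthetic sessions this rule yields ~0.12 plateaus per lap
against the generator's injected 0.06, because borderline
ordinary-amplitude events inside the post-onset drift window occasionally
pass the four criteria and drag the minimum down -- recorded amplitude
statistics are more bimodal than the generator's lognormal spread, so
this gap is expected at simulation level.

Membrane-potential plateau detection removes spikes (0.26 ms before to
3 ms after each upward crossing of dVm/dt = 25 V/s), linearly
interpolates the gaps, applies the printed baseline correction (5th
percentile of spike-onset voltages minus -50 mV) when spikes are present,
then finds epochs above -35 mV. Crossings separated by less than 150 ms
merge into one plateau (consecutive theta cycles); a plateau is
long-lasting if its summed above-threshold duration exceeds 150 ms. The
merge is idempotent.

# The three models

**Three-pool kinetic model.** Pools A (available), T (transient) and S
(sustained) with a 1-h activation phase (forward Euler, dt = 0.01 h, 100
steps) and a decay phase (2,300 steps). Activation rates come from
`|ln((2511 - day-1 PCs)/2511)|` split by the double-exponential amplitude
fractions -- the magnitude is used because the logarithm of a fraction is
negative while the pools must deplete -- and are rescaled daily by
`a = 1 - (T+S)/expected total` and `b = a x 0.6`, with `b`'s multiplier
the model's single free parameter (fit by scalar optimization of the
m.s.e.). Decay rates are `1/tau` with the taus in days, and one decay
phase integrates them over exactly one day (step 1/2300 day). The
alternative -- treating the 2,300 x 0.01-h steps as 23/24 of a day of
decay -- would make the model's effective time constants 4.3% slower than
the cohort fit it is configured from, contradicting the reported
self-consistency (t_trans = 0.67 d, t_sust = 4.6 d); we therefore treat
"per day" rates as acting once per daily cycle. Conservation of
A + T + S holds to machine precision and is asserted in the tests. The
day-1 cohort is tracked separately through the decay phases; refitting
its survivor counts returns the configured taus to better than 0.1%
(the residual is forward-Euler discretization bias). Default amplitude
fractions (0.77/0.23) solve the reported day-2 (~35%) and day-7 (~6%)
survivor fractions under the fitted taus.

**Cascade-type state model.** Each cell occupies a state counting its
days of PF activity and rests between sessions in a reliable or
unreliable pool; 88% start in unreliable state 0 and 12% in unreliable
state 1. Reliable cells reconstitute their field (probability 1, same
location). Unreliable cells at state i are recruited with
`p = 1 - prod_j [1 - r Sal(x_j) Loc(x_j)]`,
`r = 1 - (1 - alpha beta_k)^(1/50)`, drawing a location proportional to
`Sal x Loc`. The printed coefficient formulas for `q_i`, `alpha_i`,
`beta_k` and `gamma_l` are used verbatim. Recruitment from resting state
i uses the *destination* state's parameters (alpha_{i+1}, q_{i+1}); with
source-state indexing, `q_0 > 1` makes alpha_0 ~ 0 and day-1 counts
collapse far below the observed ~767 per condition, while destination
indexing reproduces them -- both conventions are implemented behind a
switch. `alpha beta` is clamped below 1 before the 50th root (printed
alpha exceeds 1 at high states and beta_1 > 1). Salience multiplies by
delta = 1.7 inside the zones [30,60] and [120,150] cm and is normalized
by the zone fraction so its track average is exactly 1; the history
weight multiplies by gamma_l within 30 cm of the previous field and is
normalized by the *empirical* within-window fraction of the evaluation
points (the printed 1/3 is the continuous-track value of the same
normalizer), keeping the mean-1 identity exact on the binned track.
Cells without a previous field have Loc = 1 everywhere. beta_k's per-run
adjustment is not specified; we use the printed average-beta formula for
every run.

**Progressive-stabilization alternative.** Two macro-states (no PF /
active PF with consecutive-day stability index i), recruitment
`p_1 = 0.3186 beta_k`, decay `q_i = 0.67^i`. With the printed beta
formula the daily counts decline across the week (the paper's per-run
beta controller is unspecified); the model's role here is the
distributional contrast with the cascade -- its days-active distribution
is detectably different under matched population size, which the tests
assert.

# The synthetic-data generator

The generator emulates the study conditions as defaults: 2,511 cells, 7
days, 126 laps in 12--18-lap alternating blocks, 30 Hz, 180 cm/50 bins,
induced width = 0.80 x speed + 18.95 cm, plateau-amplitude events at 0.06
per lap, 3-s.d.-thresholdable baseline noise, and anticipatory licking
before the active reward. Cells are assigned per condition to sustained
(day-to-day survival 0.9, centre jitter s.d. 5.9 cm with a 1-cm backward
bias, clamped to +/-30 cm of the anchor), transient (1--2 consecutive
days) or silent classes. Fields are Gaussian bumps in position whose
width is the FWHM; the induction lap carries a large (3 dF/F) event, the
five following laps always fire (the 3-of-5 structure of real
inductions), later laps fire with the configured reliability (0.85), and
the post-induction centre of mass starts 2 cm backward and relaxes
geometrically (the data constrain the sign and population distribution
of the shift, not a per-lap rule). Per-lap running speed varies by
+/-25% and event amplitudes are lognormal (sigma 0.2). Behavior streams
are generated by integrating a speed profile that dips ahead of the
reward; licks are Bernoulli per frame with an elevated anticipatory
rate. One RNG stream per session is derived from (seed, mouse, day) so a
single session can be regenerated stably.

What the generator does *not* emulate: imaging artifacts, motion,
indicator dynamics (rise/decay kinetics), multi-field cells, slow drift
of the field centre within a session beyond the induction transient, and
realistic (bimodal) event-amplitude statistics. Passing the recovery
tests therefore shows that the pipeline implements the stated criteria
correctly on data obeying its assumptions -- not that those criteria are
robust to every property of recorded data.

# Problem sizes and numerical choices

Unit and property tests run the pipeline at reduced scale (tens of cells,
~30 laps, 150--300 shuffles) chosen so the whole suite completes in about
a minute while keeping every statistical check comfortably powered; the
analysis drivers under `analysis/` use 150 cells x 7 days x 60 laps; the
model-level computations (the acceptance quantities) always run at the
study scale (2,511 cells; 1,000 cascade replicates in
`scripts/acceptance.R`). Fits use `minpack.lm::nlsLM` with explicit
bounds; degenerate inputs (constant traces, empty epochs, too few paired
cells) return flagged `NA`s with warnings rather than errors wherever
absence is a scientific outcome rather than a caller mistake.
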
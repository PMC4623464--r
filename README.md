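# devalsim

Simulation and analysis of stopping-induced stimulus devaluation
experiments.

## The problem

In a three-phase paradigm from behavioral value research, geometric
shapes first acquire monetary value through an implicit reward schedule
(learning phase), half of the shapes are then repeatedly paired with
action stopping in a stop-signal task (treatment phase), and finally all
shapes are valued in an incentive-compatible six-option auction
(valuation phase). Pairing a shape with stopping lowers its subsequent
bids — *stopping-induced devaluation* — and the effect is larger in
participants with explicit knowledge of the trained values.

`devalsim` provides, for researchers who work with this paradigm:

- reproducible generation of all three trial schedules from a single
  seeded configuration (two shipped presets differing in trial counts);
- a race-model participant simulator — independent ex-Gaussian go and
  stop processes, per-hand ±50 ms SSD staircase from 250 ms,
  knowledge-dependent valuation with an injectable devaluation effect —
  producing trial logs in a documented CSV schema plus a simulated
  debrief with known ground truth;
- the complete analysis pipeline: mean-method SSRT
  (`SSRT = mean go RT − mean SSD`), race-model validity and exclusion
  screening, explicit/implicit classification, bidding levels (rank 1–6
  within each bid set), devaluation scores (go − stop mean level),
  per-group 1.5 × IQR outlier filtering, the 2 × 2 × 4 mixed ANOVA
  (STOPPING × VALUE within, KNOWLEDGE between) with partial eta squared
  `SS_effect / (SS_effect + SS_error)`, exact/tie-corrected Wilcoxon and
  Mann-Whitney tests with `r = Z/sqrt(N)`, within-subject pair
  contrasts, bidding-variance analyses, and a Cook's-distance-screened
  variance–devaluation correlation.

Because such studies' raw data are typically not deposited, the
simulator doubles as a test bed: every analysis can be exercised against
cohorts whose true effects are known, including null cohorts for size
checks and effect grids for power ordering.

## Worked example

```r
library(devalsim)

dataset <- simulate_cohort(65, cohort_preset("cohortB"), rng_seed = 7)
report  <- analyze_study(dataset)
print(report)
```

which prints (abridged):

```
== Treatment phase ==
  n = 65 retained (0 excluded); GoRT 472 ms, failed-stop RT 426 ms,
  p(stop) 0.505, SSD 273 ms, SSRT 199 ms
  race validity: t(64) = 29.482, p = 5.899e-39, cohen_d = 3.657
== Knowledge == 22 explicit / 43 implicit
== Valuation phase == 64 analyzed (1 IQR outliers removed)
  value_level                  F(3,186) = 1728.88, p = 1.542e-135, pes = 0.965
  stopping                     F(1,62) =  20.15, p = 3.178e-05, pes = 0.245
  knowledge                    F(1,62) =   3.75, p = 0.05746, pes = 0.057
  knowledge:stopping           F(1,62) =  18.89, p = 5.235e-05, pes = 0.234
  ...
== Control analyses ==
  stop vs go bids (Wilcoxon): z[n=65] = 3.325, p = 0.0008846, r = 0.412
  devaluation by group (Mann-Whitney): z[n=65] = 4.022, p = 5.759e-05, r = 0.499
```

Reading: the staircase held stopping success near 0.5 with a mean SSD of
273 ms, giving a mean-method SSRT of 199 ms; failed-stop responses were
faster than go responses (race-model signature); bids rise with trained
value (VALUE), stop-paired shapes earn lower bids (STOPPING), and the
devaluation is larger in explicit learners (KNOWLEDGE × STOPPING) — the
qualitative pattern the default effect sizes (0.15 for explicitly named
shapes, 0.05 otherwise) are documented to produce.

`cmd_simulate()` / `cmd_analyze()` / `cmd_replicate()` wrap the same
steps for scripted use and on-disk datasets (CSV logs + JSON debrief,
checksummed manifest); `inst/cli/devalsim` exposes them as a shell
command. See `vignettes/methods.Rmd` for the agent model, its
assumptions, and every numerical choice.

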
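---
title: "Simulating and analyzing stopping-induced stimulus devaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing stopping-induced stimulus devaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devalsim)
```

## The paradigm

`devalsim` simulates and analyzes a three-phase behavioral experiment in
which rapid action stopping reduces the subjective value of reward-
associated stimuli.

1. **Learning phase.** Eight color-shape compounds are each tied to one of
   four monetary value levels. On every trial a shape appears in one of
   four quadrants, the participant responds, and a reward is displayed.
   Rewards follow a fixed schedule: per shape, a known number of trials
   pay zero and the rest pay an integer amount drawn uniformly within
   ±25 cents of that shape's mean (50, 100, 200, or 400 cents). Value
   knowledge acquired this way is largely implicit; the schedule is
   independent of performance.
2. **Treatment phase.** The same shapes drive a stop-signal task. One
   shape per value level is *stop-paired*: 75% of its trials carry an
   auditory stop signal (37.5% of all trials); the other four shapes are
   never paired with stopping. The stop-signal delay (SSD) is tracked
   separately per responding hand by a one-up/one-down staircase (±50 ms,
   starting at 250 ms) so that stopping succeeds about half of the time.
3. **Auction phase.** Each shape is valued 80 times in total via a
   six-option bidding procedure drawn from five scaled bid sets; the
   dependent variable is the *bidding level*, the rank 1–6 of the chosen
   amount within its set.

The analysis recovers the induced devaluation as the contrast between
never-stopped and stop-paired shapes, overall and as a function of
whether participants can verbalize stimulus values (explicit vs implicit
learners, classified from a debrief).

## The agent model

Each simulated participant couples a motor model with a valuation model.

**Motor model (independent horse race).** Go finishing times and stop
latencies are ex-Gaussian (Gaussian plus exponential), the standard
descriptive family for response times. On a stop trial the response is
cancelled iff `SSD + stop latency <= go time`; ties count as stops. A go
process that has not finished by the 1000 ms deadline produces no overt
response. Defaults place mean go RT at 470 ms (`mu` 400, `sigma` 40,
`tau` 70) — inside the task's 400–650 ms monitoring band — and mean stop
latency (the agent's true SSRT) at 190 ms (`mu` 150, `sigma` 20, `tau`
40), inside the plausible 120–300 ms range for auditory-signal manual
stopping. Between-agent variation of these parameters, and small lapse
(0.6%) and direction-error (0.2%) rates, are part of the population
model. These choices imply a tracking equilibrium SSD near 280 ms, so
the staircase, starting below equilibrium at 250 ms, yields cohort mean
p(stop) slightly above 0.5.

**Valuation model.** During learning the agent keeps a running mean of
the non-zero rewards observed per shape (zero-reward trials are treated
as omissions; with 60 rewarded draws the estimate's standard error is
about 1.9 cents, so trained values are learned essentially exactly —
knowledge *grade* instead governs bid noise). How value knowledge
accrues trial-by-trial is not constrained by the design; any consistent
estimator of the schedule mean would serve, and the running mean is the
simplest such choice. In the auction, subjective worth of a shape is

```
worth = value_sensitivity * internal_value * (1 - devaluation) + noise
```

and the agent picks the offered amount closest to worth (ties to the
lower amount). `devaluation` applies only to stop-paired shapes and is
larger for shapes whose value the agent can explicitly name (defaults:
0.15 for named shapes of explicit agents, 0.05 otherwise). Bid noise is
Gaussian in cents, smaller for named shapes (25 vs 60), which is what
makes bidding *variance* an observable proxy for knowledge.

Two population-level choices deserve comment:

* `value_sensitivity` has population mean 0.6, making worth sublinear in
  nominal trained value. The bid sets span 34–324 cents while
  rewarded-trial means reach 400 cents; a unit slope would pin the
  top value level at the scale ceiling on most sets, hiding any effect
  there. A compressed mapping — consistent with the under-bidding of top
  values that the bid-set design itself anticipates — keeps all four
  levels inside the usable range.
* 8% of agents are "careless" bidders with threefold bid noise. Without
  a heavy tail, Gaussian devaluation scores would essentially never
  produce interquartile-range outliers, whereas a realistic cohort of 65
  loses a handful of participants to the 1.5 × IQR screen.

Explicit agents name each value level with probability 0.9 (extreme
levels) or 0.55 (middle levels), redrawn until at least one level is
known; the extremes-first weighting mirrors the observation that salient
value differences are what participants verbalize. The simulated debrief
reports exactly those shapes with their true relative values, so
classification ground truth is known by construction.

## Analysis pipeline

`analyze_study()` chains the full results workflow:

* **Stop metrics.** Per participant: mean correct-go RT (misses and
  direction errors excluded, reported separately), failed-stop RT,
  p(stop), mean presented SSD pooled over hands (per-hand means are kept
  as diagnostics), and mean-method SSRT = go RT − mean SSD, an identity
  the tests assert on every log. Race-model validity (failed-stop RT <
  go RT per participant, paired t-test at cohort level) and exclusion
  bounds — p(stop) in [0.4, 0.6], SSRT in [120, 300] ms, race validity —
  are configurable; the block-level monitoring rule (go RT 400–650 ms,
  p(stop) 0.4–0.6, SSD > 100 ms) is a warning report, not an exclusion.
* **Devaluation scores** (go minus stop mean level; positive =
  devaluation) are screened per knowledge group by the 1.5 × IQR rule
  with linear-interpolation quartiles (`type = 7`; the quantile method
  is exposed because conventions differ).
* **Mixed ANOVA.** The 2 (STOPPING) × 4 (VALUE) within × 2 (KNOWLEDGE)
  between design is partitioned classically: KNOWLEDGE against
  subjects-within-groups, each within effect against its
  effect-by-subjects stratum; effect sizes are partial eta squared.
  Sums of squares use the sequential (weighted-means) computation from
  marginal totals, which the tests verify against `stats::aov()`
  Error-strata fits to 1e-8 relative tolerance; with unequal group
  sizes this weighted partition is the one reported. The
  implicit-learner-only analysis is the same machinery with a single
  group (2 × 4 within design).
* **Nonparametric controls** keep the IQR outliers in: a Wilcoxon
  signed-rank test of stop vs go mean levels and a Mann-Whitney test of
  devaluation scores between knowledge groups. Both report a
  tie-corrected normal-approximation Z without continuity correction and
  `r = Z/sqrt(N)`; for 25 or fewer observations the p-value is exact,
  computed from the full null distribution via generating-function
  convolution over doubled midranks (valid under ties), which the tests
  check against exhaustive enumeration.
* **Within-subject pair contrast.** In explicit learners, each
  equal-value shape pair is *explicit* if at least one member was
  accurately named; per pair, devaluation is the percent level reduction
  `100 (L_go − L_stop) / L_go` (the never-stopped shape is the
  denominator), medians are taken across qualifying pairs per condition,
  participants with all pairs in one condition drop, and the conditions
  are compared with a one-sided paired t-test (explicit > implicit, the
  direction under test).
* **Variance analyses.** The same ANOVA with per-shape bid-level
  variance as DV; within explicit learners a paired named-vs-unnamed
  variance contrast; and, in implicit learners, the correlation between
  a compound variance measure (mean per-shape variance over the four
  extreme-value shapes — both shapes of the lowest and highest levels;
  pooling all four is a choice, as selecting single shapes would be
  equally defensible) and the devaluation score, after dropping points
  with Cook's distance above 4/N in the score-on-variance regression.
  Cohen's d is `d_z` (mean/SD of differences) for paired tests and a
  pooled d for group contrasts; every reported effect size carries its
  formula tag because conventions are not unique.

## Numerical and design choices

* Schedules are pure functions of `(config, seed)`: byte-identical CSV
  on re-run. Quadrants and sides are stratified when counts divide
  evenly and i.i.d. uniform otherwise; blocks are contiguous equal
  slices after one global shuffle, with no constraint on repeats.
* Rewards are drawn on the integer cent grid (displays show cents).
  The cohort-B schedule uses the explicit 60/12 rewarded/zero split;
  per-config counts are authoritative rather than a global zero rate.
* Stop-count arithmetic (`stop fraction × trials per shape`) must be
  integral; a non-integral product is a configuration error, not
  something to round silently.
* Staircase ties (`SSD + stop latency == go time`) count as successful
  stops; SSD is clamped to [0, 1000] ms.
* `bid_to_level` requires the chosen amount to be a set member; ties
  cannot occur because sets are strictly increasing.
* The Cook's screening threshold is the standard 4/N leverage rule.

## What the tests do and do not show

The suite asserts, under the default study conditions: the design
arithmetic (trial counts, stop fractions, pair counts); determinism per
seed; the race-model censoring property (failed-stop RT < go RT);
staircase tracking (cohort mean p(stop) within ±0.04 of 0.52, ≥90% of
agents in [0.4, 0.6]); mean-method SSRT recovery within ±15 ms of truth
over 200 agents, and its invariance to hand relabeling and approximate
linearity under a +50 ms stop-latency shift; nominal type-I error of
the STOPPING test (rejection rate in [0.02, 0.10] over 200 null cohorts
of 24); monotone recovery of injected effect gaps; and exact agreement
of the ANOVA and rank tests with independent oracles (aov strata,
exhaustive enumeration).

Problem sizes in the stochastic suites (200 agents for recovery, 200
cohorts of 24 for size, tens of agents elsewhere) were chosen once as
the smallest sizes at which the binomial/Monte-Carlo error is clearly
below the asserted tolerances.

Passing these tests shows the machinery is correct and the injected
effects are recoverable — it does not show the agent model captures
human bidding. Real participants exhibit sequential effects, fatigue,
post-error slowing, anchoring across auction trials, and learning during
the treatment phase, none of which are modeled; the debrief is
simulated, so knowledge classification here has no measurement error;
and bid noise is Gaussian apart from the careless mixture, whereas real
bid distributions can be lumpier. Quantities that depend on those
unmodeled features (e.g. the exact outlier count, or human F values)
are not reproduced, only the design-determined arithmetic and the
qualitative effect structure.
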
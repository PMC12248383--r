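---
title: "Neuroeconomic analysis of Restaurant Row foraging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuroeconomic analysis of Restaurant Row foraging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrow)
library(dplyr)
```

## The task and its data model

Restaurant Row is a closed-economy foraging task: a mouse has 30 minutes per
day to earn its food by running a counterclockwise circuit of four
flavor-distinct feeding sites ("restaurants"). At each restaurant's offer
zone (OZ) a tone announces the delay the animal would have to wait for a
pellet; its pitch encodes the cost (4000 Hz for 1 s, +387 Hz per additional
second, so 1–30 s spans 4000–15223 Hz). The animal either skips onward or
enters the wait zone (WZ), where the pitch counts down and the animal may
still quit at any moment before the delay elapses. Offers are drawn uniformly
from a range that widens in blocks over 45 days (1 s only on days 1–7; 1–5 s
on days 8–12; 1–15 s on days 13–17; 1–30 s on days 18–45), turning a
reward-rich environment progressively reward-scarce. Twenty-minute task-free
probes on day 0 and day 8 measure place preference acquired during week 1.

Everything in this package operates on one tidy trial table — one row per
restaurant encounter carrying the offer, the tone, the OZ choice and latency,
the WZ outcome and time spent, consumption and travel times, and the session
clock. `validate_trials()` is the single source of truth for its invariants
(tone–offer consistency, serial restaurant order, outcome/timing coherence,
budget conservation); every estimator's preconditions are a subset of those
rules. Six mutually exclusive epochs tile each session — enter, skip, quit,
earn, consumption, and travel time — and `time_budget_partition()`
reconstructs them exactly from the stored latencies.

## Thresholds: Heaviside indifference points

Choices in either zone are summarized by the offer at which acceptance
crosses 50%: a Heaviside step fit. `fit_step_threshold()` minimizes the 0–1
loss of the rule *accept iff offer < θ* over the half-integer grid
`0.5, 1.5, …, max + 0.5`. Numerical conventions, chosen here because the
degenerate cases need deterministic answers:

* the half-integer grid makes every integer offer unambiguous under the
  strict inequality;
* ties in the loss are broken by the middle element of the minimizing set,
  taking the upper of the two middles when the set has even size (the fit in
  `fit_step_threshold(c(2, 5, 8, 12, 20, 26), c(1, 1, 1, 1, 0, 0), 30)`
  has minimizing set 12.5…19.5 and returns 16.5);
* single-class data return the nearer grid endpoint flagged `clamped` rather
  than erroring, because all-accept and all-skip animals are real;
* fits with fewer than `min_trials = 5` observations are reported missing,
  never extrapolated.

OZ fits use enter/skip on all encounters; WZ fits use earn/quit on entered
trials only. Thresholds pooled over days 18–45 (the 1–30 s block, where cost
variation identifies the step) are the default θ for all value computations;
per-day fits feed the optimality time courses.

## Quit economics

With a mouse's WZ threshold θ in hand, an offer's value is `θ − offer`
(negative = above one's willingness to wait) and the value remaining at a
quit is `θ − time left`. A quit with both quantities negative abandons a wait
that was not worth finishing — economically advantageous, the dominant
category when quitting is gated on remaining value. The boundary (value
exactly 0) counts as "positive/below threshold"; this is a documented
convention, switchable in principle but immaterial on half-integer grids.

## Sunk-cost survival analysis

`stay_survival_surface()` bins all accepted trials into (time spent `s`,
time left `l`) cells with a 1-s sliding window: a trial with offer `o` still
in the WZ after `s` whole seconds contributes to cell `(s, l = o − s)`. Earn
trials contribute survived-states `s = 0…o−1` (at `s = o` the outcome is
realized, not a decision state); quit times are floored. The cell value is
the probability of ultimately earning. The 0-s column — trials at the moment
of entry — is the control condition: comparing `p(earn)` at matched time
left across different time spent isolates the effect of time already
invested from temporal distance to the goal.

The delta envelope is computed *within mouse-restaurant units*: each unit's
sunk cells are compared to that same unit's 0-s control over the time-left
values where both hold at least `min_count = 5` trials, unit scores are
averaged into per-mouse scores, and those into the cohort envelope, with a
nonparametric bootstrap over mice (1000 draws, seeded) for the interval.
This within-unit design is essential, not cosmetic: pooling trials across
units lets patient units dominate the high-`s` cells and manufactures a
positive "sunk-cost" effect out of pure between-unit heterogeneity. We
verified this directly — the pooled estimator shows deltas up to ~0.06 with
confidence intervals excluding zero on cohorts whose generative escalation
parameter is exactly zero, while the within-unit estimator is centered on
zero there (the null-calibration test in the suite).

Two structural behaviors of the envelope are worth knowing. First, at large
`s` the only cells still holding `min_count` trials tend to have time left
at or below threshold, where both sunk and control probabilities are ~1; the
common-`l` average is therefore pulled to zero, and the envelope of a
positive-escalation cohort is hump-shaped — a rising limb over the populated
`s` range, then a sparsity-driven return to zero — rather than monotone.
Second, the same machinery applied to OZ deliberation time is a negative
control: it shows no positive effect, though a small negative artifact
(≈ −0.01) appears because the fixed session budget preferentially truncates
long trials, weakly coupling deliberation time to acceptance even when the
generator draws them independently.

## Regret sequences

Two trial-pair scenarios capture the behavioral footprint of economic
mistakes. Type 1: the animal skips a high-value offer (value ≥ 0) and then
faces a low-value offer at the next restaurant; the control arm accepted the
high-value offer. Type 2: the animal enters and then quits a low-value offer
(value < 0); the control arm skipped it. In both, the read-out is acceptance
of the next low-value offer. `extract_sequences()` requires consecutive
encounters within a session and stratifies both arms by (restaurant at t−1,
value bin at t−1, value bin at t) with 2-s bins, so comparisons match on
offer values and flavors; `sequence_delta()` differences the arms within
stratum and combines strata by the effective pair count
`n_v·n_nv/(n_v+n_nv)`. `cohort_sign_test()` reports both the one-sample t
statistic and the exact sign test against zero.

The generator's compensation parameter `regret_rho` adds to the accept
probability only on the trial after an enter-then-quit of a negative-value
offer, so by construction it moves type-2 deltas and not type-1 deltas — the
dissociation the analysis is designed to detect. At 20 mice × 28 scarcity
days the type-2 delta recovers `rho = 0.2` within ±0.05 while the type-1
delta stays at zero (acceptance suite).

## Threshold optimality

A deterministic forager that accepts any offer at or below `T` and always
waits it out earns, under continuous uniform offers on `[0, M]` with
per-restaurant overhead `h` and consumption time `c`, at rate proportional to
`T / (M·h + T²/2 + c·T)`, maximized at `T* = √(2Mh)` independent of `c`.
`simulate_yield_surface()` verifies this by brute simulation (the same
replicate offer streams are reused across candidate thresholds, which makes
the argmax comparison nearly deterministic); with the package defaults
(`h = 5/3` s, `c = 1.5` s, 1–30 s offers, 30-min budget) the sweep peaks at
10 s. The timing constants are the package's own calibration — chosen so the
1–30 s environment's optimum sits at 10 s, with `c` provably unable to move
it — and are exposed in `yield_sim_params()` and reported in output metadata.

Subjective value weights each restaurant's pellets by the mouse's day-7 earn
ratios (revealed preference when every offer costs 1 s).
`subjective_value_thresholds()` searches the per-restaurant threshold
4-vector maximizing total weighted value under the shared budget: coordinate
ascent on the simulated objective by default, an exhaustive grid for small
custom grids, and a deterministic closed-form variant (`method = "analytic"`)
that the test suite cross-checks against an independent exhaustive search.
Optimality is then scored per day as the Euclidean distance between the
observed four-restaurant threshold vector and each theoretical vector,
separately by zone; days with any missing restaurant are reported incomplete,
never interpolated.

## The synthetic cohort: what it emulates and what it does not

The generator is the minimal mechanism producing every analyzed signature,
not a fitted model of mice:

* **Accept rule** — `accept_scale[r] · plogis(β(θ_oz[r] − offer)) + ρ·memory`,
  where `accept_scale[r] = w_r / max(w)` is a flavor-preference gate. The
  gate is what lets day-7 earnings (all offers 1 s) reflect preference
  order, since a logistic in the offer cannot separate flavors at a single
  offer; with uniform weights it is 1 and the rule is a pure softened
  threshold. Recovery presets use uniform weights because a gate below 1
  deliberately depresses acceptance of below-threshold offers and shifts the
  0–1-loss fit.
* **Quit rule** — per-second hazard
  `h·1[l > θ_wz]·max(0, 1 − κ·s)`: quits only occur while the remaining
  delay exceeds threshold (so they are advantageous by construction), and
  time already invested scales the hazard down; `κ` is the generative
  sunk-cost escalation.
* **Learning** — week-1 OZ latencies and travel times decay exponentially
  (`1 + 1.5·e^{−(day−1)/2}`), giving the acquisition ramp in earnings; it is
  a qualitative target only.
* **Timing** — latencies and travel times are gamma-distributed around
  configurable means (2 s and 4 s; consumption 1.5 s), recorded at
  microsecond resolution so trial tables round-trip exactly through text.
  With these means a scarcity-block session holds roughly 200–230 encounters
  (≈ 55 laps), and the 30-min budget binds.
* **Truncation** — the trial in progress when the budget expires is stored
  flagged and excluded from estimators (simplest consistent convention; the
  alternative would be censoring).
* **Probes** — day-0 WZ occupancy is uniform in expectation; day-8 occupancy
  adds `cpp_gain` seconds per day-7 pellet in that restaurant, capped at the
  probe duration. Whether the day-8 probe preceded or followed that day's
  task session is not modeled; both sessions are simply generated.
* **Group presets** — the four sex-by-treatment presets differ in `κ` and
  `ρ` to echo the reported qualitative pattern (type-2 sensitivity absent in
  control females, sunk-cost and type-2 sensitivity enhanced in treated
  females). They are illustrative, not estimates.

Deliberate omissions: no spatial trajectories (distance traveled is
approximated as laps × lap length and flagged as such), no
vicarious-trial-and-error measures, no physiological covariates, and no
fitting of policies to real data. Passing tests on this cohort certify the
estimators' logic and calibration — binning, matching, controls, bootstrap —
under a known ground truth; they cannot certify that real mice satisfy the
generator's assumptions (memoryless hazards, stationary thresholds,
independence of latency and choice).

## Problem sizes and numerical settings

The test suite exercises the estimators at the sizes that make their claims
meaningful while staying desk-scale: the null-calibration cohort is 40 mice
× 28 scarcity days (≈ 240k trials); parameter recovery uses 20 mice × 28
days; the type-I calibration of the cohort test runs 100 independent
10-mouse null cohorts; the yield sweep uses 150–1000 replicate sessions per
grid point; estimator-oracle equivalence covers 1000 random instances.
Bootstrap intervals use 1000 draws (300 in small unit tests). All randomness
descends from fixed seeds; the pipeline derives stage seeds from one root
seed so stages are independently re-runnable.

Known numerical caveats: percentile bootstrap intervals over few mice
(< ~10) undercover slightly; fixed-seed 95%-coverage checks of null effects
fail ~5% of seeds by construction (the suite asserts such point checks at
the 99% level and verifies 5%-level calibration across 100 cohorts instead);
and the envelope's common-`l` restriction, while essential against
composition bias, is what pulls the envelope to zero where cells thin out —
`n_mice` and `n_l` are reported alongside every delta so the support is
auditable.
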
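---
title: "Simulating numeric reasoning, calculation and judgment: model, hemodynamics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating numeric reasoning, calculation and judgment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actrbold)
```

## The cognitive model

`actrbold` simulates three self-paced numeric tasks as serial critical
paths of module events in an ACT-R-style architecture.  Five modules carry
the load: *visual* (encoding numbers and symbols), *declarative* (fact
retrieval), *problem state* (holding intermediate representations),
*procedural* (production firings that glue steps together) and *motor*
(button presses).  Cognition is modeled as strictly serial: every event
starts when its predecessor ends, so a trial's reaction time is the sum of
the durations on its path.  This is a deliberate simplification — the full
architecture allows some parallelism between modules — but it makes every
prediction auditable by hand and it preserves the property the analysis
turns on: how much total time each module is busy per trial.

The three strategies:

* **Rea (series reasoning, e.g. `5:11:17`)** — encode the first two
  numbers; retrieve the *direction* of the pair (ascending/descending, a
  fast order fact) and store it; retrieve the *relation* (the signed
  difference, a slow deliberate fact) and store it; encode the third
  number; retrieve the second direction and compare.  If the directions
  disagree the series is rejected immediately — no second relation
  retrieval.  Otherwise the second relation is retrieved and compared, the
  answer is represented in the problem state, and a response is made.
* **Cal (three-term calculation, e.g. `13 − 5 + 7`)** — encode the five
  equation symbols, retrieve the intermediate result by rote memory (high
  activation, fast), store it, retrieve the final result (a computed fact,
  slower), store it, respond.
* **Jud (detect the digit 10)** — encode the digits sequentially, halting
  as soon as a 10 is found; represent the answer and respond.  No
  declarative retrievals at all.

Each block starts with a 2 s cue, modeled as a visual encode, a
problem-state update and an instruction retrieval that complete before the
30 s task window opens.  After the first press, an option-selection phase
(encode the two options, press the matching side) ends the trial, followed
by a 2 s inter-stimulus interval.  Trials repeat until the window closes; a
trial still in progress at window close is truncated and not counted.  A
stimulus unanswered after 10 s times out and counts as an error.

## Timing parameters

| parameter | default | meaning |
|---|---|---|
| `latency_factor` (F) | 0.4 s | scales retrieval latency `F·exp(−A)` |
| `problem_state_dt` | 0.400 s | one problem-state change |
| `visual_encode_dt` | 0.085 s | one visual encoding |
| `production_dt` | 0.050 s | one production firing |
| `motor_dt` | 0.260 s | one button press |

The fixed durations are the architecture's conventional defaults; the
latency factor and problem-state change are the two task-fitted values.
The activation levels per fact class (`direction` 0.98, `relation` −0.20,
`rote` 0.69, `calc` −0.56, `instruction` 1.0) are the package's calibrated
defaults: they are the free parameters of the model, chosen once so that
the simulated per-condition reaction times and block throughputs sit in
the empirically observed regime (about 5 Rea, 5.5 Cal and 8.5 Jud trials
per 30 s block, with RT ordered Rea > Cal > Jud).  They translate to
retrieval latencies of roughly 150 ms (direction), 490 ms (relation),
200 ms (rote) and 700 ms (computed result).

## Noise and errors

Retrieval latency noise is Gaussian on the activation
(`activation_noise_sd`, default 0.25), making latencies lognormal.
Mis-retrievals are modeled separately as a logistic commission
probability `plogis((threshold − A)/scale)` with threshold −2.2 and scale
0.8 — a shallow curve, so the *number* of vulnerable retrievals matters
roughly as much as their activation.  Rea, with two low-activation
relation retrievals per trial, therefore ends up least accurate; Cal with
one is intermediate; Jud, with no retrievals, is near ceiling apart from a
1% response slip.  A mis-retrieval keeps its drawn latency (it is a wrong
fact, not a failure that waits out the retrieval threshold), which keeps
the throughput predictions clean.  Setting `activation_noise_sd = 0`
switches the engine into a fully deterministic mode and disables all error
processes — the convention the property tests rely on.

## From trace to BOLD

Each module's merged block trace becomes a binary demand function `D(t)`
on a 10 ms grid (half-open event intervals, cell-midpoint rule, so a
grid-aligned 0.4 s event contributes exactly 40 cells).  Predicted raw
BOLD is the discrete convolution with the gamma response
`H(t) = m(t/s)^α e^{−t/s}`, with the kernel sampled at cell midpoints
(midpoint-rule quadrature, error `O(dt²)`); the result is sampled at
TR = 2 s.  Defaults: shape `α = 6` and scale `s = 0.75 s`, giving a
4.5 s peak typical of cortical responses; magnitude `m = 1e−4`, which
together with the unit baseline offset yields percent-signal changes of
order 1%.  `m` is the parameter one would refit per region of interest;
all predictions are linear in it, so condition *orderings* and AUC ratios
are invariant to its value.

A per-block series spans 7 pre-cue rest scans, the 2 s cue, the 30 s task
and the 30 s rest (38 scans).  Percent change divides by the mean of the
7 pre-task scans and the *last* 8 scans of the post-task rest — taking the
late rest scans lets the hemodynamic tail decay before the baseline is
measured; the early/late choice within the rest block is a convention the
source design leaves open.  Because a model prediction is zero at rest, an
additive baseline offset (default 1 unit) stands in for mean MR signal;
AUC comparisons are invariant to this choice up to scale.  The AUC is the
trapezoidal integral of the percent-change series between task start and
task end, window edges snapped to the nearest scan.

Numerical conventions worth stating: time is 0-based with half-open event
intervals `[onset, onset + duration)`; demand is strictly binary, so event
edges round to the grid (duration error at most half a cell per edge) —
grid-refinement consistency therefore holds exactly for grid-aligned
events and to `O(grid_dt)` otherwise; the convolution kernel is truncated
at 30 s, where the gamma tail is below 1e−10 of its peak; whether demand is
convolved per trial or per merged block trace makes no difference to block
AUC by linearity, and the merged-block route is used throughout.

## Analysis and calibration

`repeated_measures_anova()` is the classical one-way subject-by-condition
F test with `(k−1, (k−1)(n−1))` degrees of freedom, computed via
`stats::aov` with a subject error stratum and no sphericity correction
(with three conditions and fifteen subjects this is the conventional
`F(2, 28)`).  `compare_auc()` applies it per module/ROI and reports the
direction of the reasoning-minus-calculation difference.

`fit_parameters()` estimates the latency factor and problem-state change
by grid search: at every grid point the experiment is re-simulated (with a
common seed across points, so comparisons use common random numbers) and
the loss is the summed squared error of per-condition mean RT and trials
per block, each z-scaled by the spread of the target values so the two
measures weigh equally — the source analysis reports only that behavior
was fit, so the objective is a package choice and is configurable.  Ties
break toward the smaller latency factor, then the smaller problem-state
change.

## The synthetic-participant generator

`simulate_participants()` emulates a 15-subject sample: each subject is
one full simulated experiment; a subject-level lognormal factor (mean 1,
`rt_noise_sd = 0.1` on the log scale) scales recorded RTs; trials flip
correctness with probability 0.02; and ROI BOLD gets additive white
Gaussian scan noise (`bold_noise_sd = 0.002` raw units, i.e. a few percent
of the evoked response) before percent change.  These defaults are chosen
once as plausible magnitudes for a healthy young-adult sample.  What the
generator deliberately does *not* emulate: temporally autocorrelated
physiological noise, scanner drift, motion, voxel-level spatial structure,
learning or fatigue across blocks, and RT-throughput coupling in the
jitter (the factor rescales recorded RTs without re-running the
self-paced window).  Passing tests on these data therefore demonstrate
pipeline correctness and parameter recoverability under known ground
truth — not robustness to the full noise structure of real fMRI.

## Problem sizes used by the test suite

The packaged checks simulate 100 experiments for the behavioral
reproduction (about 1800 blocks per condition pair of runs), 10,000
stimuli per condition and 1,000 run designs for the invariant sweeps, 20
synthetic datasets for noisy parameter recovery on a 5×5 grid (0.2–0.6 s
in steps of 0.1), and 500 null replicates for the size of the AUC
comparison.  These sizes were chosen to keep Monte-Carlo error well below
the tolerances being asserted.

## Known limitations

* The serial critical path understates module parallelism; absolute RTs
  are interpretable, but fine-grained event overlap is not modeled.
* The error model is phenomenological (logistic commission on activation);
  the architecture's full retrieval-failure dynamics, utility learning and
  strategy variability are out of scope.
* The Rea response options are the validity labels and the one invalid
  series sits at a random pool position; both are conventions where the
  task description is silent, exposed as configuration.
* Voxelwise maps, preprocessing and GLM-based whole-brain inference are
  intentionally absent: the package operates at the region/module level
  only.
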
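---
title: "Simulating and analyzing head-fixed operant and consummatory behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing head-fixed operant and consummatory behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headfixr)
library(dplyr)
```

## The platform being modeled

Head-fixed behavioral platforms for mice combine a running wheel with a
rotary encoder (the operant manipulandum), a retractable lick spout gated by
a solenoid, a wheel brake, tone and laser outputs, and — in the multi-spout
variant — a radial head that presents one of five spouts per trial. A
microcontroller runs the task state machine and streams timestamped hardware
and behavioral events to disk; all analysis is performed on that event log.

`headfixr` re-implements the *logic* of such a platform without the
hardware. Task state machines consume actions from a parametric virtual
mouse and emit event logs in a stable CSV format; the analysis layer then
computes every behavioral readout from the log alone, exactly as it would
from a recorded session. Because the virtual mouse has known parameters,
every analysis output can be checked against the ground truth that generated
it — the core design idea of the package.

## The event log

A session log is a tibble of `(time_ms, code, value)` rows plus `key=value`
header metadata. The clock is integer milliseconds, which represents all of
the platform's timing constants (200 ms inter-pulse interval, 3 s and 5 s
access periods, 5–10 s ITIs) exactly. The event vocabulary is a closed
enumeration (`event_codes()`); a `schema_version` header field allows the
format to evolve. Logs are validated structurally (`validate_log()`):
monotone timestamps, one `session_start`/`session_end` pair, strict
trial-marker alternation with consecutive indices, and on/off alternation of
the tone, laser and brake lines (an actuator left on is terminated by
session end). Violations are returned as data rather than raised, so logs
can be audited programmatically.

## Task state machines

All eight trainings/tasks share one encoder model (64 ticks per rotation —
stated for the place-preference task and adopted globally, configurable) and
one reward envelope: brake (where applicable), spout extension, five ~1.5 µL
pulses at 200 ms spacing, and a tone-on access period.

* **Free access** (10 min): every lick triggers one same-millisecond
  delivery.
* **Spout training** (60 trials): non-contingent pulse trains with 5 s
  access and 20–40 s uniform ITIs.
* **Fixed ratio** (30 min): active-direction ticks accumulate toward the
  ratio (default 1/2 turn). Completion runs the braked reward envelope for
  3 s; completing the same ratio in the inactive direction engages the brake
  for the identical 3 s envelope with no delivery. The wheel physically
  cannot turn while braked, so no ticks occur (or count) during either
  envelope. Reversal training is a configuration change
  (`active_direction = -1`), not a separate state machine.
* **Progressive ratio**: reinforcer *i* costs the *i*-th schedule entry;
  the session ends at 1 hr or 15 min after the last reinforcer, whichever
  comes first. The breakpoint is the cost of the last completed ratio.
* **Optogenetic positive/negative reinforcement** (20 min): the brake stays
  off. Positive: ratio completion triggers a 1 s laser + tone; rotation
  during the stimulation is logged but not counted. Negative: the laser is
  on from session start and completion pauses it for exactly 3 s; the
  concurrent tone's duration is not specified by the procedure, so here it
  spans the pause.
* **Wheel time preference** (20 min): wheel position modulo one rotation is
  split into two half-rotation zones; the paired zone drives continuous
  laser and its tone, the unpaired zone the second tone, and the session
  starts in the unpaired zone at the tick adjacent to the paired boundary.
* **Multi-spout brief access** (100 trials): the planned spout is presented
  for 3 s; each lick triggers one same-millisecond delivery on that spout;
  5–10 s ITIs retract all spouts. Per-trial solution and spout identities
  are carried in the log header so a single file is self-contained.

Fractional ratio costs are converted to encoder ticks by
`round(cost * ticks_per_rotation)`; with a 64-position encoder the printed
costs 0.25, 0.5 and 0.81 become 16, 32 and 52 ticks. Actuator latencies are
zero: the logic, not the physics, is under test (the physical platform's
spout extension completes in under 180 ms and is irrelevant to the
contingencies modeled here). When a lick and a spout retraction fall in the
same millisecond the lick is processed first, making tie order
deterministic.

## Schedules

`ratio_schedule()` reproduces the printed semilogarithmic prefix
0.25, 0.5, 0.81, 1.21, 1.71, 2.3, 3.1, 4.1 as a stored lookup — the printed
terms are normative. Beyond the eighth term the schedule must continue
deterministically; the log-increments of the printed prefix converge to
about 0.28, so later terms grow by the asymptotic ratio
`cost_i = round(cost_(i-1) * 1.32, 2)`. Only the printed prefix should be
treated as ground truth; the continuation is a documented convention of this
package. The linear schedule is `0.5 * i`.

`schedule_multispout()` implements per-block pseudorandomization: each block
of 10 trials contains every solution exactly twice, shuffled uniformly and
independently per block. No cross-block anti-repeat constraint is imposed,
because only the per-block composition is specified.
`counterbalance_spouts()` samples a Latin square (each solution on each
spout exactly once across the session cycle) as a seeded random row/column
permutation of the cyclic square — reproducibility, not uniformity over all
squares, is the requirement.

## The virtual mouse

The agent (`agent_params()`, `preset()`) is behavioral phenomenology, not a
decision model. Licking is a bout-structured renewal process: bouts initiate
at a per-solution Poisson rate (the palatability map), contain a geometric
number of licks, and within-bout inter-lick intervals are log-normal with
mean 140 ms (typical rhythmic ~7 Hz mouse licking) and CV 0.25. Rotation is
a tick point process with a direction bias; `reinforcement_gain`
multiplicatively scales the tick rate after each reward or stimulation
(capped at 10×), and an optional satiation constant decays the bout rate
across a session. By default agents are stationary — engine tests need
stationary ground truth; the `learner` preset adds a gain ramp for
illustrative learning curves.

For the place-preference task, `zone_drift` modulates the rotation *rate* by
zone rather than biasing direction: the rate is scaled by `1 - d` while
stimulated and `1 + d` otherwise, with `d = zone_drift * laser_hz / 40`
(40 Hz is the strongest stimulation used). Occupancy of a zone is inversely
proportional to the speed of traversal, so the expected paired-zone dwell
fraction is `(1 + d) / 2`: `d = 0` gives the 600 s indifference point of a
1200 s session by symmetry, `d = 1` clamps the agent in the paired zone, and
`d = -1` excludes it. This rate-modulation model was chosen over a
directional drift because its stationary occupancy is analytically
transparent and directly testable.

The engine samples these processes in event-driven form (exponential gaps
between ticks and bouts) rather than stepping a 1 ms clock; `agent_step()`
exposes the equivalent per-timestep view of the same distributions for
inspecting the agent in isolation. Setting `deterministic_ticks = TRUE`
replaces exponential tick gaps with their mean, which makes closed-form
hand simulations of reward counts possible in tests.

## Analysis conventions

* Lick latency is measured from the spout **extension command**, matching
  how the platform timestamps trials.
* Inter-lick intervals are computed within trials only for trial-based
  tasks; the spout is retracted between trials, so across-trial gaps are
  not microstructure.
* The bout criterion (a pause of ≥ 1000 ms closes a bout) is a common
  convention rather than a printed value, and is exposed as a parameter so
  its sensitivity can be examined.
* Per-solution summaries are computed per session and then averaged across
  the counterbalanced session cycle, and aggregate by solution, never by
  spout.
* Licks cannot register while the spout is retracted — in the simulator
  this is structural, whereas on hardware it is merely overwhelmingly
  likely; analysis code nevertheless windows licks to trials.

## Photometry chain

`synth_trace()` generates a sensor channel as cubic drift + per-trial
double-exponential transients + white noise, and a control channel as drift
+ noise only (no event-locked structure, mirroring the role of the 405 nm
channel as a motion-artifact check). The processing chain is fixed and
ordered: fit and subtract a third-degree polynomial per channel over the
full session; z-score using the whole-session mean and SD (a constant
channel is an error, not NaN propagation); build peri-event histograms
aligned to access onset, resampled to 20 samples/s; shift each trial row by
its mean over the 3 s before onset; then summarize the access period by its
average and peak and correlate the per-trial average with the lick count
(Pearson, two-sided). The control channel is validated but never subtracted
from the sensor channel. The resampling method is linear interpolation onto
the 20 Hz grid (the native synthetic rate is 100 Hz) and the default window
is 3 s before to 5 s after onset; both are parameters, since the upstream
procedure does not pin them down.

## Problem sizes, tolerances and numerical choices

The test suite builds every fixture programmatically. Stochastic
expectations use Monte-Carlo tolerances derived from measured standard
errors (e.g. the 600 s indifference expectation is checked over 80 seeded
sessions against a 4-standard-error band); the acceptance script uses 200
sessions for the same quantity and 100 sessions for ITI bounds. Determinism
is bit-exact: one seed drives schedule construction, agent sampling and
trace synthesis, and identical inputs reproduce identical files.

## Limitations

The virtual mouse is stationary by design and does not learn, deliberate,
or fatigue (beyond the optional satiation decay); passing tests demonstrate
that the state machines, schedulers and analysis code are correct and
internally consistent, not that real mice behave like the agent. Hardware
physics (spout travel, brake latency, encoder debounce), freely moving task
variants, group inferential statistics, and acquisition-system file formats
are out of scope.

## A worked session

```{r example}
cfg <- session_config("multispout", seed = 1)
log <- run_multispout(cfg, preset("concentration_tracker"))
glance(log)

trial_table(log) |>
  summarize_by_solution()

ratio_schedule("semilog", 8)$cost
```
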
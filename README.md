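# headfixr

A hardware-free simulator and analysis toolkit for head-fixed mouse
behavioral tasks run on a wheel-and-spout platform: free-access lick
training, retractable-spout training, fixed- and progressive-ratio operant
conditioning for sucrose, optogenetic positive and negative reinforcement,
wheel-based real-time place preference, and brief-access multi-spout
consumption — plus the fiber-photometry processing chain used to relate
mesolimbic signals to licking in the multi-spout task.

It is written for behavioral neuroscientists who want to prototype task
logic, validate analysis pipelines against known ground truth, or teach
these paradigms without animals or hardware. Task state machines run on a
millisecond clock, consume actions from a parametric virtual mouse, and emit
timestamped event logs in a stable CSV interchange format; the analysis
layer computes every behavioral readout from logs alone.

## What it computes

* **Operant schedules.** Fixed ratios in fractional wheel turns (64 encoder
  ticks per rotation; e.g. FR 1/2 = 32 ticks) and progressive-ratio
  schedules. The semilogarithmic schedule is
  `0.25, 0.5, 0.81, 1.21, 1.71, 2.3, 3.1, 4.1, …` and the linear schedule
  `0.5·i`; the **breakpoint** is the cost of the last ratio completed before
  the session ends (1 hr cap, or 15 min without a reinforcer).
* **Trial scheduling.** Brief-access sessions of 100 × 3 s trials with each
  of 5 solutions presented exactly twice per 10-trial block, ITIs uniform on
  5–10 s, and spout–solution assignment counterbalanced over 5 sessions as a
  Latin square.
* **Lick microstructure.** Inter-lick intervals, bout segmentation under a
  pause criterion, per-trial lick counts and first-lick latencies, binned
  lick rates, and per-solution summaries aggregated by solution across
  counterbalanced sessions.
* **Place preference.** Dwell time per wheel zone; for a 20 min session,
  paired-zone time above 600 s indicates preference, below 600 s avoidance.
* **Photometry.** Cubic detrend → whole-session z-score → peri-event
  histograms at 20 samples/s, baseline-shifted on the 3 s before access
  onset → mean/peak access-period signal → Pearson correlation with licking.

## Worked example

```r
library(headfixr)

cfg <- session_config("multispout", seed = 1)
log <- run_multispout(cfg, preset("concentration_tracker"))
glance(log)
#> # A tibble: 1 × 9
#>   session_id    task_kind  seed duration_ms n_events n_trials n_licks n_solenoid
#> 1 multispout-s1 multispout    1     1048661     1658      100     528        528

trial_table(log) |> summarize_by_solution()
#> # A tibble: 5 × 5
#>   solution_index mean_licks_per_trial mean_latency_ms prop_trials_with_lick
#> 1              0                 1              1285.                  0.25
#> 2              1                 3.95           1046.                  0.5
#> 3              2                 4.65           1224.                  0.65
#> 4              3                 7.15           1115.                  0.9
#> 5              4                 9.65            845.                  0.95
```

The agent's palatability map (bout-initiation rate rising with solution
index, emulating increasing sucrose concentration) is recovered as a
monotone mean-licks-per-trial profile, every lick was answered by exactly
one solenoid delivery (528 = 528), and the session spans 100 trials.

A place-preference session with an agent that lingers under 40 Hz
stimulation:

```r
w <- run_wtp(session_config("wtp", seed = 1, laser_hz = 40L), preset("preferrer"))
wtp_dwell(w)
#> # A tibble: 1 × 3
#>   paired_s unpaired_s total_s
#> 1    1014.       186.    1200
```

1014 s of the 1200 s session in the stimulation-paired zone — well above
the 600 s indifference point — while paired + unpaired time exactly
conserves the session duration.

Simulation, analysis and a synthetic-photometry demonstration are also
available from the shell via `inst/scripts/headfixr-cli.R`
(`simulate`, `analyze`, `demo-photometry` subcommands).

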
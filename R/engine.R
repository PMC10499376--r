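# Event recorder: amortized-growth vectors behind a closure.
new_recorder <- function(cap = 1024L) {
  t <- integer(cap)
  code <- character(cap)
  value <- integer(cap)
  n <- 0L
  grow <- function(need) {
    while (need > length(t)) {
      t <<- c(t, integer(length(t)))
      code <<- c(code, character(length(code)))
      value <<- c(value, integer(length(value)))
    }
  }
  add <- function(time, cd, val = 0L) {
    n <<- n + 1L
    grow(n)
    t[n] <<- as.integer(time)
    code[n] <<- cd
    value[n] <<- as.integer(val)
    invisible(NULL)
  }
  add_many <- function(times, cds, vals = 0L) {
    m <- length(times)
    if (m == 0L) return(invisible(NULL))
    grow(n + m)
    idx <- n + seq_len(m)
    t[idx] <<- as.integer(times)
    code[idx] <<- rep_len(cds, m)
    value[idx] <<- rep_len(as.integer(vals), m)
    n <<- n + m
    invisible(NULL)
  }
  events <- function() {
    keep <- seq_len(n)
    tibble::tibble(time_ms = t[keep], code = code[keep], value = value[keep])
  }
  list(add = add, add_many = add_many, events = events)
}

# Curated config fields copied into every log header so analysis is
# self-contained from the file.
META_CONFIG_KEYS <- c(
  "duration_ms", "n_trials", "fixed_ratio_turns", "access_ms",
  "pulses_per_reward", "inter_pulse_ms", "iti_lo_ms", "iti_hi_ms",
  "tone_hz", "tone2_hz", "stim_ms", "pause_ms", "laser_hz",
  "ticks_per_rotation", "pr_kind", "pr_timeout_ms", "active_direction",
  "n_solutions"
)

# Clip to session end, stable-sort by time, close the log, attach summary.
finalize_log <- function(rec, cfg, end_ms, extra_meta = list(), summary = NULL) {
  ev <- rec$events()
  ev <- ev[ev$time_ms <= end_ms, , drop = FALSE]
  ev <- ev[order(ev$time_ms), , drop = FALSE] # stable: ties keep emission order
  ev <- dplyr::bind_rows(
    ev,
    tibble::tibble(time_ms = as.integer(end_ms), code = "session_end", value = 0L)
  )
  meta <- c(
    list(
      session_id = paste0(cfg$task_kind, "-s", cfg$seed),
      task_kind = cfg$task_kind,
      config_digest = config_digest(unclass(cfg)),
      seed = cfg$seed,
      schema_version = LOG_SCHEMA_VERSION
    ),
    lapply(cfg[META_CONFIG_KEYS], function(x) paste(format(x, scientific = FALSE, trim = TRUE), collapse = ",")),
    extra_meta
  )
  log <- session_log(ev, meta, check = TRUE)
  if (!is.null(summary)) attr(log, "summary") <- summary
  log
}

#' Engine summary of a session
#'
#' Returns the one-row summary the engine attached to a freshly simulated
#' log; for logs loaded from disk the summary is recomputed from the events
#' with the analysis layer.
#'
#' @param log A `session_log`.
#' @return One-row tibble whose columns depend on the task.
#' @export
session_summary <- function(log) {
  s <- attr(log, "summary", exact = TRUE)
  if (!is.null(s)) return(s)
  task <- log_meta(log)$task_kind
  g <- glance.session_log(log)
  switch(task,
    operant_pr = {
      bp <- breakpoint(log)
      dplyr::bind_cols(g, bp)
    },
    wtp = dplyr::bind_cols(g, wtp_dwell(log)),
    opto_positive = ,
    opto_negative = dplyr::bind_cols(g, opto_counts(log)),
    g
  )
}

# Emit one access period starting at t0: optional brake envelope, spout
# extension, tone, non-contingent pulse train and/or lick-contingent
# deliveries, then retraction. Returns the clock after the access period.
emit_access <- function(rec, cfg, agent, t0, solution = 0L, spout = 0L,
                        brake = FALSE, contingent = FALSE,
                        pulses = !contingent, session_t0 = 0) {
  t_end <- t0 + cfg$access_ms
  if (brake) rec$add(t0, "brake_on", 0L)
  rec$add(t0, "spout_extend_cmd", spout)
  rec$add(t0, "tone_on", cfg$tone_hz)
  if (pulses) {
    pt <- t0 + (seq_len(cfg$pulses_per_reward) - 1L) * cfg$inter_pulse_ms
    rec$add_many(pt, "solenoid_open", spout)
  }
  licks <- gen_lick_train(agent, solution, t0, t_end, session_t0_ms = session_t0)
  if (length(licks) > 0) {
    if (contingent) {
      rec$add_many(rep(licks, each = 2L), rep(c("lick", "solenoid_open"), length(licks)), spout)
    } else {
      rec$add_many(licks, "lick", spout)
    }
  }
  rec$add(t_end, "tone_off", 0L)
  rec$add(t_end, "spout_retract_cmd", spout)
  if (brake) rec$add(t_end, "brake_off", 0L)
  t_end
}

#' Simulate a free-access lick-training session
#'
#' A 10 min (default) session in which the spout is always available and
#' every lick immediately triggers one solenoid delivery in the same
#' millisecond -- the closed-loop approximation of free-access consumption.
#'
#' @param config A `session_config` with `task_kind = "free_access"`.
#' @param agent An `agent_params`.
#' @return A `session_log`; `session_summary()` reports the lick count.
#' @export
run_free_access <- function(config, agent = preset("learner")) {
  stopifnot(config$task_kind == "free_access")
  set.seed(config$seed)
  rec <- new_recorder()
  rec$add(0L, "session_start", 0L)
  licks <- gen_lick_train(agent, 0L, 0, config$duration_ms)
  if (length(licks) > 0) {
    rec$add_many(rep(licks, each = 2L), rep(c("lick", "solenoid_open"), length(licks)), 0L)
  }
  finalize_log(rec, config, config$duration_ms,
    summary = tibble::tibble(n_licks = length(licks), n_deliveries = length(licks))
  )
}

#' Simulate a retractable-spout training session
#'
#' Sixty trials (default): on each, the spout extends, a 5 kHz tone plays,
#' five solenoid pulses are delivered at a 200 ms inter-pulse interval
#' regardless of behavior, and the animal has a 5 s access period; trials
#' are separated by 20-40 s uniform inter-trial intervals.
#'
#' @param config A `session_config` with `task_kind = "spout_training"`.
#' @param agent An `agent_params`.
#' @return A `session_log`.
#' @export
run_spout_training <- function(config, agent = preset("learner")) {
  stopifnot(config$task_kind == "spout_training")
  set.seed(config$seed)
  rec <- new_recorder()
  rec$add(0L, "session_start", 0L)
  t <- 0L
  for (i in seq_len(config$n_trials) - 1L) {
    rec$add(t, "trial_start", i)
    t_end <- emit_access(rec, config, agent, t,
      solution = 0L, spout = 0L,
      brake = FALSE, contingent = FALSE, pulses = TRUE
    )
    rec$add(t_end, "trial_end", i)
    t <- t_end + sample_iti(config$iti_lo_ms, config$iti_hi_ms)
  }
  end_ms <- t_end
  finalize_log(rec, config, end_ms,
    extra_meta = list(
      solution_by_trial = paste(rep(0L, config$n_trials), collapse = ","),
      spout_by_trial = paste(rep(0L, config$n_trials), collapse = ",")
    ),
    summary = tibble::tibble(n_trials = config$n_trials)
  )
}

#' Simulate a multi-spout brief-access session
#'
#' One hundred trials (default) of 3 s access to one of five solutions per
#' the supplied trial plan: the radial head presents the planned spout, each
#' lick during access triggers one solenoid delivery on that spout, and
#' trials are separated by the plan's 5-10 s inter-trial intervals during
#' which all spouts are retracted.
#'
#' @param config A `session_config` with `task_kind = "multispout"`.
#' @param agent An `agent_params` (its palatability map drives licking).
#' @param plan Trial plan from [trial_plan()]; defaults to the plan generated
#'   from the config's own seed with an identity spout map.
#' @return A `session_log` whose header carries the per-trial solution and
#'   spout identities.
#' @export
run_multispout <- function(config, agent = preset("concentration_tracker"),
                           plan = NULL) {
  stopifnot(config$task_kind == "multispout")
  if (is.null(plan)) {
    plan <- trial_plan(
      n_trials = config$n_trials, n_solutions = config$n_solutions,
      block_size = config$n_solutions * 2L, per_block = 2L,
      iti_lo_ms = config$iti_lo_ms, iti_hi_ms = config$iti_hi_ms,
      seed = config$seed
    )
  }
  if (nrow(plan) != config$n_trials) {
    stop(
      "trial plan has ", nrow(plan), " trials but config$n_trials is ",
      config$n_trials
    )
  }
  set.seed(config$seed + 1L) # plan consumed the base seed stream
  rec <- new_recorder(4096L)
  rec$add(0L, "session_start", 0L)
  t <- 0L
  for (k in seq_len(nrow(plan))) {
    i <- plan$trial_index[k]
    rec$add(t, "trial_start", i)
    t_end <- emit_access(rec, config, agent, t,
      solution = plan$solution_index[k], spout = plan$spout_index[k],
      brake = FALSE, contingent = TRUE, session_t0 = 0
    )
    rec$add(t_end, "trial_end", i)
    t <- t_end + plan$iti_ms[k]
  }
  finalize_log(rec, config, t_end,
    extra_meta = list(
      solution_by_trial = paste(plan$solution_index, collapse = ","),
      spout_by_trial = paste(plan$spout_index, collapse = ",")
    ),
    summary = tibble::tibble(n_trials = config$n_trials)
  )
}

# Shared operant wheel loop for the sucrose fixed/progressive ratio tasks.
# thresholds_ticks: vector of tick costs per successive reinforcer (recycled
# last element for FR). Returns list(log-ready recorder state, counts).
run_wheel_operant <- function(config, agent, thresholds_ticks, costs,
                              progressive = FALSE) {
  set.seed(config$seed)
  rec <- new_recorder(4096L)
  rec$add(0L, "session_start", 0L)
  dur <- config$duration_ms
  deadline <- if (progressive) min(dur, config$pr_timeout_ms) else dur
  t <- 0
  act <- 0L
  inact <- 0L
  rewards <- 0L
  penalties <- 0L
  mult <- 1
  end_ms <- deadline
  repeat {
    rate <- agent$rot_rate_ticks_per_s * mult
    if (rate <= 0) break
    gap <- if (agent$deterministic_ticks) 1000 / rate else stats::rexp(1, rate) * 1000
    tt <- t + max(1, round(gap))
    if (tt >= deadline) break
    thr_i <- min(rewards + 1L, length(thresholds_ticks))
    thr <- thresholds_ticks[thr_i]
    is_active <- stats::runif(1) < agent$active_bias
    dirval <- if (is_active) config$active_direction else -config$active_direction
    rec$add(tt, "rotation_tick", dirval)
    if (is_active) act <- act + 1L else inact <- inact + 1L
    if (act >= thr) {
      emit_access(rec, config, agent, tt,
        solution = 0L, spout = 0L,
        brake = TRUE, contingent = FALSE, pulses = TRUE
      )
      rewards <- rewards + 1L
      act <- 0L
      mult <- min(mult * agent$reinforcement_gain, 10)
      t <- tt + config$access_ms
      if (progressive) deadline <- min(dur, tt + config$pr_timeout_ms)
      if (progressive && rewards >= length(thresholds_ticks)) break
    } else if (inact >= thr) {
      # inactive ratio: brake for the full rewarded-trial brake envelope,
      # no spout, no tone, no delivery
      rec$add(tt, "brake_on", 0L)
      rec$add(tt + config$access_ms, "brake_off", 0L)
      penalties <- penalties + 1L
      inact <- 0L
      t <- tt + config$access_ms
    } else {
      t <- tt
    }
  }
  end_ms <- deadline
  bp <- if (rewards > 0L) costs[min(rewards, length(costs))] else 0
  list(
    rec = rec, end_ms = end_ms, rewards = rewards, penalties = penalties,
    breakpoint = bp
  )
}

#' Simulate a fixed-ratio operant session for sucrose
#'
#' Rotation in the active direction accumulates toward the fixed ratio
#' (default 1/2 turn at 64 ticks/rotation). Completion engages the wheel
#' brake, extends the spout, delivers five 200 ms-spaced pulses, and holds a
#' 3 s tone-on access period with the brake engaged; completing the same
#' ratio in the inactive direction engages the brake for the identical
#' envelope but delivers nothing. The wheel cannot turn while braked, so no
#' ticks are emitted (or counted) during reward or penalty periods.
#'
#' @param config A `session_config` with `task_kind = "operant_fr"`.
#' @param agent An `agent_params`.
#' @return A `session_log`; `session_summary()` reports reward and penalty
#'   counts.
#' @export
run_operant_fr <- function(config, agent = preset("learner")) {
  stopifnot(config$task_kind == "operant_fr")
  thr <- max(1L, round(config$fixed_ratio_turns * config$ticks_per_rotation))
  res <- run_wheel_operant(config, agent, thr, costs = config$fixed_ratio_turns,
    progressive = FALSE
  )
  finalize_log(res$rec, config, config$duration_ms,
    summary = tibble::tibble(
      n_reinforcers = res$rewards, n_inactive_penalties = res$penalties
    )
  )
}

#' Simulate a progressive-ratio session for sucrose
#'
#' Reinforcer `i` costs the `i`-th entry of [ratio_schedule()] for the
#' configured schedule kind. The session ends at 1 hr, or 15 min after the
#' last earned reinforcer (measured from session start if none is earned),
#' whichever comes first. The breakpoint is the cost of the last completed
#' ratio (0 if no reinforcer was earned).
#'
#' @param config A `session_config` with `task_kind = "operant_pr"`.
#' @param agent An `agent_params`.
#' @return A `session_log`; `session_summary()` reports `n_reinforcers` and
#'   `breakpoint`.
#' @export
run_operant_pr <- function(config, agent = preset("learner")) {
  stopifnot(config$task_kind == "operant_pr")
  sched <- ratio_schedule(config$pr_kind, 64L)
  thr <- pmax(1L, round(sched$cost * config$ticks_per_rotation))
  res <- run_wheel_operant(config, agent, thr, costs = sched$cost,
    progressive = TRUE
  )
  finalize_log(res$rec, config, res$end_ms,
    summary = tibble::tibble(
      n_reinforcers = res$rewards, breakpoint = res$breakpoint,
      session_end_ms = res$end_ms
    )
  )
}

# Shared loop for the optogenetic reinforcement tasks: unbraked wheel,
# responses during the stimulation (positive) or pause (negative) window are
# logged but not counted toward the next ratio.
run_opto <- function(config, agent, negative = FALSE) {
  set.seed(config$seed)
  rec <- new_recorder(4096L)
  rec$add(0L, "session_start", 0L)
  dur <- config$duration_ms
  window_ms <- if (negative) config$pause_ms else config$stim_ms
  if (negative) rec$add(0L, "laser_on", config$laser_hz)
  thr <- max(1L, round(config$fixed_ratio_turns * config$ticks_per_rotation))
  t <- 0
  act <- 0L
  events_earned <- 0L
  window_until <- -Inf
  mult <- 1
  repeat {
    rate <- agent$rot_rate_ticks_per_s * mult
    if (rate <= 0) break
    gap <- if (agent$deterministic_ticks) 1000 / rate else stats::rexp(1, rate) * 1000
    tt <- t + max(1, round(gap))
    if (tt >= dur) break
    is_active <- stats::runif(1) < agent$active_bias
    dirval <- if (is_active) config$active_direction else -config$active_direction
    rec$add(tt, "rotation_tick", dirval)
    if (is_active && tt >= window_until) {
      act <- act + 1L
      if (act >= thr) {
        if (negative) {
          rec$add(tt, "laser_off", 0L)
          rec$add(tt, "tone_on", config$tone_hz)
          rec$add(tt + window_ms, "tone_off", 0L)
          rec$add(tt + window_ms, "laser_on", config$laser_hz)
        } else {
          rec$add(tt, "laser_on", config$laser_hz)
          rec$add(tt, "tone_on", config$tone_hz)
          rec$add(tt + window_ms, "laser_off", 0L)
          rec$add(tt + window_ms, "tone_off", 0L)
        }
        events_earned <- events_earned + 1L
        act <- 0L
        window_until <- tt + window_ms
        mult <- min(mult * agent$reinforcement_gain, 10)
      }
    }
    t <- tt
  }
  key <- if (negative) "n_pauses" else "n_stimulations"
  finalize_log(rec, config, dur,
    summary = tibble::tibble(!!key := events_earned)
  )
}

#' Simulate head-fixed positive optogenetic reinforcement
#'
#' Completing the fixed ratio in the active direction triggers 1 s of laser
#' stimulation with a concurrent 5 kHz tone; the brake stays disengaged, and
#' rotation during the 1 s stimulation is recorded but does not count toward
#' the next stimulation.
#'
#' @param config A `session_config` with `task_kind = "opto_positive"`.
#' @param agent An `agent_params`.
#' @return A `session_log`; `session_summary()` reports `n_stimulations`.
#' @export
run_opto_positive <- function(config, agent = preset("learner")) {
  stopifnot(config$task_kind == "opto_positive")
  run_opto(config, agent, negative = FALSE)
}

#' Simulate head-fixed negative optogenetic reinforcement
#'
#' Continuous laser stimulation begins at session start; completing the
#' fixed ratio in the active direction pauses stimulation for exactly 3 s
#' with a concurrent tone. Rotation during a pause is recorded but does not
#' count toward an additional pause.
#'
#' @param config A `session_config` with `task_kind = "opto_negative"`.
#' @param agent An `agent_params`.
#' @return A `session_log`; `session_summary()` reports `n_pauses`.
#' @export
run_opto_negative <- function(config, agent = preset("learner")) {
  stopifnot(config$task_kind == "opto_negative")
  run_opto(config, agent, negative = TRUE)
}

#' Simulate a wheel-time-preference session
#'
#' The wheel circumference is split into two half-rotation zones; the
#' session starts with the wheel in the unpaired zone at the tick adjacent
#' to the paired-zone boundary. Occupancy of the paired zone triggers
#' continuous laser stimulation and its tone; the unpaired zone plays the
#' second tone. Every boundary crossing emits a `zone_enter` event
#' (value 0 = paired, 1 = unpaired). A 20 min session is the default; over
#' it, time in the paired zone above 600 s indicates preference and below
#' 600 s avoidance.
#'
#' @param config A `session_config` with `task_kind = "wtp"`.
#' @param agent An `agent_params`; its `zone_drift` (scaled by
#'   `laser_hz / 40`) sets the preference phenotype.
#' @return A `session_log`; `session_summary()` reports dwell times.
#' @export
run_wtp <- function(config, agent = preset("indifferent")) {
  stopifnot(config$task_kind == "wtp")
  set.seed(config$seed)
  rec <- new_recorder(8192L)
  rec$add(0L, "session_start", 0L)
  tpr <- config$ticks_per_rotation
  half <- tpr %/% 2L
  zone_of <- function(pos) if ((pos %% tpr) < half) 0L else 1L
  pos <- half # unpaired, adjacent to the paired boundary
  zone <- zone_of(pos)
  dur <- config$duration_ms
  d_eff <- agent$zone_drift * min(config$laser_hz, 40) / 40
  rec$add(0L, "zone_enter", zone)
  rec$add(0L, "tone_on", if (zone == 0L) config$tone_hz else config$tone2_hz)
  if (zone == 0L && config$laser_hz > 0) rec$add(0L, "laser_on", config$laser_hz)
  t <- 0
  dwell <- c(0, 0) # paired, unpaired (ms)
  repeat {
    rate <- agent$rot_rate_ticks_per_s * (if (zone == 0L) 1 - d_eff else 1 + d_eff)
    if (rate <= 0) break
    gap <- if (agent$deterministic_ticks) 1000 / rate else stats::rexp(1, rate) * 1000
    tt <- t + max(1, round(gap))
    if (tt >= dur) break
    dir <- if (stats::runif(1) < agent$active_bias) 1L else -1L
    rec$add(tt, "rotation_tick", dir)
    dwell[zone + 1L] <- dwell[zone + 1L] + (tt - t)
    pos <- pos + dir
    nz <- zone_of(pos)
    if (nz != zone) {
      rec$add(tt, "zone_enter", nz)
      rec$add(tt, "tone_off", 0L)
      rec$add(tt, "tone_on", if (nz == 0L) config$tone_hz else config$tone2_hz)
      if (config$laser_hz > 0) {
        if (nz == 0L) rec$add(tt, "laser_on", config$laser_hz) else rec$add(tt, "laser_off", 0L)
      }
      zone <- nz
    }
    t <- tt
  }
  dwell[zone + 1L] <- dwell[zone + 1L] + (dur - t)
  finalize_log(rec, config, dur,
    summary = tibble::tibble(
      paired_s = dwell[1] / 1000, unpaired_s = dwell[2] / 1000,
      n_crossings = sum(rec$events()$code == "zone_enter") - 1L
    )
  )
}

#' Simulate one session of any task
#'
#' Dispatches on `config$task_kind` to the matching task engine.
#'
#' @param config A `session_config`.
#' @param agent An `agent_params`; defaults to a task-appropriate preset.
#' @param plan Optional trial plan (multi-spout only).
#' @return A `session_log`.
#' @export
simulate_session <- function(config, agent = NULL, plan = NULL) {
  switch(config$task_kind,
    free_access = run_free_access(config, agent %||% preset("learner")),
    spout_training = run_spout_training(config, agent %||% preset("learner")),
    operant_fr = run_operant_fr(config, agent %||% preset("learner")),
    operant_pr = run_operant_pr(config, agent %||% preset("learner")),
    opto_positive = run_opto_positive(config, agent %||% preset("learner")),
    opto_negative = run_opto_negative(config, agent %||% preset("learner")),
    wtp = run_wtp(config, agent %||% preset("indifferent")),
    multispout = run_multispout(config, agent %||% preset("concentration_tracker"), plan = plan),
    stop("unknown task_kind: ", config$task_kind)
  )
}
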
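test_that("free access couples every lick to one delivery in the same ms", {
  cfg <- session_config("free_access", seed = 31)
  log <- run_free_access(cfg, preset("learner"))
  licks <- log[log$code == "lick", ]
  sols <- log[log$code == "solenoid_open", ]
  expect_gt(nrow(licks), 0)
  expect_equal(nrow(sols), nrow(licks))
  expect_equal(sols$time_ms, licks$time_ms)
  expect_equal(max(log$time_ms), 600000L)

  mute <- run_free_access(cfg, agent_params(bout_rate_hz = 0))
  expect_equal(sum(mute$code == "solenoid_open"), 0L)
  expect_equal(max(mute$time_ms), 600000L)
})

test_that("spout training delivers the tone-paired pulse train on schedule", {
  cfg <- session_config("spout_training", seed = 32)
  log <- run_spout_training(cfg, preset("learner"))
  expect_equal(sum(log$code == "trial_start"), 60L)
  # consecutive pulses within each trial are exactly 200 ms apart
  tw <- headfixr::trial_table(log)
  sols <- log[log$code == "solenoid_open", ]
  starts <- log$time_ms[log$code == "trial_start"]
  for (t0 in starts[1:10]) {
    pt <- sols$time_ms[sols$time_ms >= t0 & sols$time_ms < t0 + 5000]
    expect_equal(diff(pt), rep(200L, 4))
  }
  # ITIs respect the configured 20-40 s bounds
  ends <- log$time_ms[log$code == "trial_end"]
  itis <- starts[-1] - ends[-length(ends)]
  expect_true(all(itis >= 20000 & itis <= 40000))
  # deliveries are non-contingent: a mute agent still gets all trials
  mute <- run_spout_training(cfg, agent_params(bout_rate_hz = 0))
  expect_equal(sum(mute$code == "trial_start"), 60L)
  expect_equal(sum(mute$code == "solenoid_open"), 300L)
  expect_equal(mean(trial_table(mute)$n_licks > 0), 0)
})

test_that("fixed-ratio rewards match a step-by-step replay of the tick stream", {
  # deterministic slow rotator, FR 1/2, hand-checkable
  cfg <- session_config("operant_fr", seed = 33, duration_ms = 120000L)
  agent <- agent_params(
    rot_rate_ticks_per_s = 4, active_bias = 1, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  )
  log <- run_operant_fr(cfg, agent)
  # 32 ticks at 250 ms = 8000 ms to ratio, then 3000 ms braked access:
  # rewards at 8000, 19000, 30000, ... => floor((120000-8000)/11000)+1 = 11
  expect_equal(sum(log$code == "spout_extend_cmd"), 11L)
  oracle <- replay_wheel_counts(log, thresholds = 32L)
  expect_equal(sum(log$code == "spout_extend_cmd"), oracle$rewards)

  # immobile agent: nothing happens
  still <- run_operant_fr(cfg, preset("non_responder"))
  expect_equal(sum(still$code == "spout_extend_cmd"), 0L)
  expect_equal(sum(still$code == "brake_on"), 0L)

  # inactive-only agent: brakes engage, nothing is delivered
  inactive <- run_operant_fr(cfg, agent_params(
    rot_rate_ticks_per_s = 4, active_bias = 0, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  ))
  expect_gt(sum(inactive$code == "brake_on"), 0L)
  expect_equal(sum(inactive$code == "solenoid_open"), 0L)
  expect_equal(sum(inactive$code == "spout_extend_cmd"), 0L)
  # penalty brake spans the rewarded-trial envelope (3 s); a final brake
  # cut short by session end has no brake_off row
  b_on <- inactive$time_ms[inactive$code == "brake_on"]
  b_off <- inactive$time_ms[inactive$code == "brake_off"]
  n <- length(b_off)
  expect_gte(length(b_on), n)
  expect_equal(b_off - b_on[seq_len(n)], rep(3000L, n))
})

test_that("no rotation ticks are emitted while the wheel is braked", {
  cfg <- session_config("operant_fr", seed = 34, duration_ms = 600000L)
  log <- run_operant_fr(cfg, preset("learner"))
  braked <- FALSE
  violations <- 0L
  for (i in seq_len(nrow(log))) {
    if (log$code[i] == "brake_on") braked <- TRUE
    if (log$code[i] == "brake_off") braked <- FALSE
    if (log$code[i] == "rotation_tick" && braked) violations <- violations + 1L
  }
  expect_equal(violations, 0L)
})

test_that("progressive ratio terminates and reports breakpoints as specified", {
  # non-responder: session ends at exactly 15 min without a reinforcer
  cfg <- session_config("operant_pr", seed = 35)
  still <- run_operant_pr(cfg, preset("non_responder"))
  expect_equal(max(still$time_ms), 900000L)
  s <- session_summary(still)
  expect_equal(s$n_reinforcers, 0L)
  expect_equal(s$breakpoint, 0)

  # agent that completes exactly three semilog ratios before session end:
  # 16+32+52 ticks at 100 ms/tick plus 3x3000 ms access = 19000 ms
  cfg3 <- session_config("operant_pr", seed = 36, duration_ms = 22000L)
  agent <- agent_params(
    rot_rate_ticks_per_s = 10, active_bias = 1, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  )
  log3 <- run_operant_pr(cfg3, agent)
  s3 <- session_summary(log3)
  expect_equal(s3$n_reinforcers, 3L)
  expect_equal(s3$breakpoint, 0.81)
  expect_equal(breakpoint(log3)$breakpoint, 0.81) # analysis cross-check

  # tireless fast agent runs to the 1 hr cap
  fast <- agent_params(
    rot_rate_ticks_per_s = 50, active_bias = 1, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  )
  logf <- run_operant_pr(session_config("operant_pr", seed = 37), fast)
  expect_equal(max(logf$time_ms), 3600000L)
})

test_that("positive reinforcement stimulations obey the 1 s refractory rule", {
  cfg <- session_config("opto_positive", seed = 38)
  agent <- agent_params(
    rot_rate_ticks_per_s = 4, active_bias = 1, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  )
  log <- run_opto_positive(cfg, agent)
  on_t <- log$time_ms[log$code == "laser_on"]
  off_t <- log$time_ms[log$code == "laser_off"]
  expect_equal(off_t - on_t, rep(1000L, length(on_t)))
  # rotation continues during stimulation but does not earn extra stimulations
  expect_gt(sum(log$code == "rotation_tick"), length(on_t) * 32)
  expect_true(all(diff(on_t) > 1000))
  # ticks during the stimulation window are logged but not counted
  oracle <- replay_opto_counts(log, negative = FALSE)
  expect_equal(length(on_t), oracle)
  expect_equal(session_summary(log)$n_stimulations, length(on_t))

  # a fast burst inside the stimulation window cannot earn a second one:
  # at 16 ms/tick the 32-tick ratio completes at 512 ms; the next ~60 ticks
  # fall inside [512, 1512) and are excluded
  burst <- agent_params(
    rot_rate_ticks_per_s = 64, active_bias = 1, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  )
  blog <- run_opto_positive(session_config("opto_positive", seed = 39, duration_ms = 2000L), burst)
  bon <- blog$time_ms[blog$code == "laser_on"]
  expect_equal(length(bon), 1L)
  expect_equal(bon, 512L)

  # immobile agent earns nothing
  still <- run_opto_positive(cfg, preset("non_responder"))
  expect_equal(sum(still$code == "laser_on"), 0L)
})

test_that("negative reinforcement pauses span exactly 3 s of laser-off", {
  cfg <- session_config("opto_negative", seed = 40)
  agent <- agent_params(
    rot_rate_ticks_per_s = 4, active_bias = 1, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  )
  log <- run_opto_negative(cfg, agent)
  on_t <- log$time_ms[log$code == "laser_on"]
  off_t <- log$time_ms[log$code == "laser_off"]
  expect_equal(on_t[1], 0L) # stimulation from session start
  # every pause: laser_off followed by laser_on exactly 3000 ms later
  expect_equal(on_t[-1] - off_t[seq_along(on_t[-1])], rep(3000L, length(on_t) - 1))
  oracle <- replay_opto_counts(log, negative = TRUE)
  expect_equal(session_summary(log)$n_pauses, oracle)
  expect_equal(opto_counts(log)$n_events, oracle)

  # non-responder: laser on for the whole session, zero pauses
  still <- run_opto_negative(cfg, preset("non_responder"))
  expect_equal(sum(still$code == "laser_off"), 0L)
  expect_equal(session_summary(still)$n_pauses, 0L)
})

test_that("wheel-time-preference geometry, dwell conservation and limits", {
  cfg <- session_config("wtp", seed = 41)
  # immobile agent starts in the unpaired zone: zero paired time
  still <- run_wtp(cfg, preset("non_responder"))
  d <- wtp_dwell(still)
  expect_equal(d$paired_s, 0)
  expect_equal(d$total_s, 1200)

  # strong preferrer clamps in the paired zone after the first crossing
  clamp <- agent_params(
    rot_rate_ticks_per_s = 4, active_bias = 0.5, zone_drift = 1
  )
  clog <- run_wtp(session_config("wtp", seed = 42, laser_hz = 40L), clamp)
  cd <- wtp_dwell(clog)
  expect_gt(cd$paired_s, 1100)
  expect_equal(cd$paired_s + cd$unpaired_s, 1200)
  # once in the paired zone the laser stays on until session end
  expect_equal(sum(clog$code == "laser_on"), 1L)
  expect_equal(sum(clog$code == "laser_off"), 0L)

  # dwell conservation and summary agreement across phenotypes
  for (nm in c("indifferent", "preferrer", "avoider")) {
    log <- run_wtp(session_config("wtp", seed = 43, laser_hz = 40L), preset(nm))
    d <- wtp_dwell(log)
    expect_equal(d$paired_s + d$unpaired_s, d$total_s)
    expect_equal(d$total_s, 1200)
    s <- session_summary(log)
    expect_equal(s$paired_s, d$paired_s)
  }
  # preference/avoidance phenotypes separate around the 600 s midpoint
  pref <- wtp_dwell(run_wtp(session_config("wtp", seed = 44, laser_hz = 40L), preset("preferrer")))
  avoid <- wtp_dwell(run_wtp(session_config("wtp", seed = 44, laser_hz = 40L), preset("avoider")))
  expect_gt(pref$paired_s, 600)
  expect_lt(avoid$paired_s, 600)
})

test_that("multispout sessions follow the plan and the closed lick loop", {
  cfg <- session_config("multispout", seed = 45)
  log <- run_multispout(cfg, preset("concentration_tracker"))
  expect_equal(sum(log$code == "trial_start"), 100L)
  starts <- log$time_ms[log$code == "trial_start"]
  ends <- log$time_ms[log$code == "trial_end"]
  itis <- starts[-1] - ends[-length(ends)]
  expect_true(all(itis >= 5000 & itis <= 10000))
  expect_equal(ends - starts, rep(3000L, 100))

  # every lick triggers one same-ms delivery; none while retracted
  licks <- log[log$code == "lick", ]
  sols <- log[log$code == "solenoid_open", ]
  expect_equal(nrow(sols), nrow(licks))
  expect_equal(sols$time_ms, licks$time_ms)
  tw <- headfixr::trial_table(log)
  idx <- findInterval(sols$time_ms, starts)
  expect_true(all(sols$time_ms <= ends[idx])) # inside an access window
  # per-trial lick count equals per-trial delivery count
  expect_equal(sum(tw$n_licks), nrow(sols))

  # plan/config mismatch is an error
  short_plan <- trial_plan(n_trials = 50L, block_size = 10L, seed = 1L)
  expect_error(run_multispout(cfg, plan = short_plan), "50 trials")
})

test_that("identical config, agent and seed reproduce identical logs", {
  cfg <- session_config("multispout", seed = 46)
  a <- run_multispout(cfg, preset("concentration_tracker"))
  b <- run_multispout(cfg, preset("concentration_tracker"))
  expect_identical(tidy(a), tidy(b))
  expect_identical(log_meta(a), log_meta(b))

  w1 <- run_wtp(session_config("wtp", seed = 47), preset("indifferent"))
  w2 <- run_wtp(session_config("wtp", seed = 47), preset("indifferent"))
  expect_identical(tidy(w1), tidy(w2))
})
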
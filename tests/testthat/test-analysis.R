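test_that("all metrics reproduce hand-computed values on the frozen fixture", {
  log <- read_log(fixture_log_path())
  expect_equal(nrow(validate_log(log)), 0L)

  tt <- trial_table(log)
  expect_equal(tt$n_licks, c(0L, 3L, 2L, 5L, 1L))
  expect_equal(tt$latency_first_lick_ms, c(NA, 250, 100, 500, 10))
  expect_equal(tt$last_lick_ms, c(NA, 550, 2900, 1100, 10))
  expect_equal(tt$solution_index, 0:4)

  ili <- inter_lick_intervals(log)
  expect_equal(ili$ili_ms, c(150, 150, 2800, 150, 150, 150, 150))
  expect_equal(ili$trial_index, c(1L, 1L, 2L, 3L, 3L, 3L, 3L))

  bouts <- segment_bouts(log$time_ms[log$code == "lick"], pause_ms = 1000)
  expect_equal(nrow(bouts), 5L)
  expect_equal(bouts$n_licks, c(3L, 1L, 1L, 5L, 1L))
  expect_equal(bouts$start_ms[1], 8250)
  expect_equal(bouts$end_ms[1], 8550)

  s <- summarize_by_solution(tt)
  expect_equal(sum(s$mean_licks_per_trial), 0 + 3 + 2 + 5 + 1)
  expect_equal(mean(tt$n_licks), 2.2)
  expect_equal(mean(tt$n_licks > 0), 0.8)
  expect_equal(mean(tt$latency_first_lick_ms, na.rm = TRUE), 215)

  bins <- binned_trial_licks(tt, bin = 10L)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$mean_licks, 2.2)
})

test_that("inter-lick intervals follow the microstructure definition", {
  meta <- list(
    session_id = "i", task_kind = "free_access", config_digest = "0",
    seed = 1, schema_version = 1
  )
  log <- session_log(
    tibble::tibble(
      time_ms = c(0L, 0L, 150L, 300L, 1000L),
      code = c("session_start", "lick", "lick", "lick", "session_end"),
      value = 0L
    ),
    metadata = meta
  )
  expect_equal(inter_lick_intervals(log)$ili_ms, c(150L, 150L))
  one <- session_log(
    tibble::tibble(
      time_ms = c(0L, 10L, 100L),
      code = c("session_start", "lick", "session_end"), value = 0L
    ),
    metadata = meta
  )
  expect_equal(nrow(inter_lick_intervals(one)), 0L)
})

test_that("bout segmentation matches the brute-force gap-scan oracle", {
  expect_equal(
    segment_bouts(c(0, 150, 300, 2000, 2150), pause_ms = 1000)$n_licks,
    c(3L, 2L)
  )
  expect_equal(nrow(segment_bouts(numeric(0))), 0L)
  expect_error(segment_bouts(c(5, 1)), "sorted")

  for (s in 1:20) {
    set.seed(s)
    licks <- sort(sample(0:20000, sample(1:120, 1)))
    pause <- sample(c(250, 500, 1000, 2000), 1)
    got <- segment_bouts(licks, pause_ms = pause)
    want <- bouts_oracle(licks, pause)
    expect_equal(got, want)
    expect_equal(sum(got$n_licks), length(licks)) # partition covers all licks
  }
})

test_that("trial_table agrees with the engine's delivery accounting", {
  cfg <- session_config("multispout", seed = 51)
  log <- run_multispout(cfg, preset("concentration_tracker"))
  tt <- trial_table(log)
  starts <- log$time_ms[log$code == "trial_start"]
  ends <- log$time_ms[log$code == "trial_end"]
  sols <- log[log$code == "solenoid_open", ]
  per_trial <- vapply(seq_along(starts), function(k) {
    sum(sols$time_ms >= starts[k] & sols$time_ms <= ends[k])
  }, integer(1))
  expect_equal(tt$n_licks, per_trial) # replay oracle
  expect_true(all(is.na(tt$latency_first_lick_ms) == (tt$n_licks == 0)))
})

test_that("per-solution summaries aggregate by solution across counterbalanced sessions", {
  cb <- counterbalance_spouts(5, seed = 60)
  logs <- lapply(1:5, function(sess) {
    map <- cb$spout_index[cb$session == sess][order(cb$solution_index[cb$session == sess])]
    plan <- trial_plan(spout_map = map, seed = 60 + sess)
    run_multispout(
      session_config("multispout", seed = 60 + sess),
      preset("concentration_tracker"), plan
    )
  })
  trials <- purrr::imap_dfr(logs, function(l, i) {
    tt <- trial_table(l)
    tt$session <- i
    tt
  })
  s <- summarize_by_solution(trials)
  expect_equal(s$n_sessions, rep(5L, 5))
  # monotone palatability map is recovered as monotone mean licks
  expect_true(all(diff(s$mean_licks_per_trial) > 0))

  # spout-only records plus the counterbalance table recover the same means
  blind <- dplyr::select(trials, !"solution_index")
  s2 <- summarize_by_solution(blind, counterbalance = cb)
  expect_equal(
    dplyr::arrange(s2, solution_index)$mean_licks_per_trial,
    s$mean_licks_per_trial
  )

  # exchangeable (flat) palatability: no solution separates from the rest
  flat_logs <- lapply(1:3, function(i) {
    run_multispout(
      session_config("multispout", seed = 70 + i),
      agent_params(bout_rate_hz = 0.5, rot_rate_ticks_per_s = 0)
    )
  })
  ftrials <- purrr::imap_dfr(flat_logs, function(l, i) {
    tt <- trial_table(l)
    tt$session <- i
    tt
  })
  fs <- summarize_by_solution(ftrials)
  se <- ftrials |>
    dplyr::group_by(solution_index) |>
    dplyr::summarise(se = sd(n_licks) / sqrt(dplyr::n()), .groups = "drop")
  expect_lt(diff(range(fs$mean_licks_per_trial)), 6 * mean(se$se))
})

test_that("trial binning and peri-access lick rates behave as defined", {
  cfg <- session_config("multispout", seed = 52)
  log <- run_multispout(cfg, preset("concentration_tracker"))
  tt <- trial_table(log)
  bins <- binned_trial_licks(tt, bin = 10L)
  expect_equal(nrow(bins), 10L) # 100 trials in 10-trial bins

  # satiating agent shows a decreasing within-session profile
  sat <- agent_params(
    bout_rate_hz = c(1, 1.2, 1.5, 1.8, 2), satiation_tau_s = 200,
    rot_rate_ticks_per_s = 0
  )
  slog <- run_multispout(session_config("multispout", seed = 53), sat)
  sbins <- binned_trial_licks(trial_table(slog), bin = 10L)
  expect_lt(mean(sbins$mean_licks[8:10]), mean(sbins$mean_licks[1:3]))

  rate <- binned_lick_rate(log, bin_ms = 250)
  expect_equal(nrow(rate), 5L * 12L) # 5 solutions x 3000/250 bins
  # histogram oracle: total rate mass matches the lick count
  total_licks <- sum(rate$lick_rate_hz * 0.25 * 20) # 20 trials per solution
  expect_equal(total_licks, sum(tt$n_licks))
  # zero-lick log yields an all-zero curve
  mute <- run_multispout(cfg, agent_params(bout_rate_hz = 0))
  expect_true(all(binned_lick_rate(mute)$lick_rate_hz == 0))
})

test_that("wheel summaries equal a tick-stream replay", {
  cfg <- session_config("operant_fr", seed = 54, duration_ms = 300000L)
  log <- run_operant_fr(cfg, preset("learner"))
  w <- wheel_summary(log)
  ticks <- log[log$code == "rotation_tick", ]
  expect_equal(w$totals$total_active_ticks, sum(ticks$value == 1))
  expect_equal(w$totals$total_inactive_ticks, sum(ticks$value == -1))
  expect_equal(
    w$totals$terminal_position_ticks,
    sum(ticks$value == 1) - sum(ticks$value == -1)
  )
  expect_equal(nrow(w$position), nrow(ticks))

  # active-only agent accumulates no inactive ticks
  act <- run_operant_fr(cfg, agent_params(
    rot_rate_ticks_per_s = 3, active_bias = 1, deterministic_ticks = TRUE,
    bout_rate_hz = 0
  ))
  expect_equal(wheel_summary(act)$totals$total_inactive_ticks, 0L)

  # symmetric agent drifts little relative to its total rotation
  sym <- run_wtp(session_config("wtp", seed = 55), preset("indifferent"))
  ws <- wheel_summary(sym)$totals
  expect_lt(
    abs(ws$terminal_position_ticks),
    0.25 * (ws$total_active_ticks + ws$total_inactive_ticks)
  )
})

test_that("within-subject z-scores across conditions match the direct formula", {
  d <- tibble::tibble(
    subject = "m1", condition = 1:3, value = c(1, 2, 3)
  )
  z <- zscore_across_conditions(d)
  expect_equal(z$z, c(-1, 0, 1))
  expect_false(any(z$constant))

  const <- tibble::tibble(subject = "m2", condition = 1:4, value = rep(5, 4))
  zc <- zscore_across_conditions(const)
  expect_true(all(zc$constant))
  expect_equal(zc$z, rep(0, 4))

  set.seed(8)
  r <- tibble::tibble(
    subject = rep(c("a", "b"), each = 6),
    condition = rep(1:6, 2),
    value = rnorm(12)
  )
  zr <- zscore_across_conditions(r)
  for (sub in c("a", "b")) {
    v <- r$value[r$subject == sub]
    expect_equal(zr$z[zr$subject == sub], (v - mean(v)) / sd(v)) # direct oracle
    expect_equal(mean(zr$z[zr$subject == sub]), 0)
    expect_equal(sd(zr$z[zr$subject == sub]), 1)
  }
})
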
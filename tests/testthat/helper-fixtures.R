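# Shared generators and independent oracles for the suite.

# A random but structurally valid session log, for round-trip properties.
random_valid_log <- function(seed) {
  set.seed(seed)
  dur <- sample(2000:20000, 1)
  n_lick <- sample(0:30, 1)
  n_tick <- sample(0:30, 1)
  ev <- tibble::tibble(
    time_ms = integer(), code = character(), value = integer()
  )
  add <- function(t, c, v = 0L) {
    ev <<- dplyr::bind_rows(ev, tibble::tibble(
      time_ms = as.integer(t), code = c, value = as.integer(v)
    ))
  }
  add(0, "session_start")
  if (n_lick > 0) {
    for (t in sort(sample(1:(dur - 1), n_lick))) add(t, "lick", sample(0:4, 1))
  }
  if (n_tick > 0) {
    for (t in sort(sample(1:(dur - 1), n_tick))) {
      add(t, "rotation_tick", sample(c(-1L, 1L), 1))
    }
  }
  ev <- ev[c(1, 1 + order(ev$time_ms[-1])), ]
  add(dur, "session_end")
  session_log(ev, metadata = list(
    session_id = paste0("rand-", seed), task_kind = "free_access",
    config_digest = "deadbeef", seed = seed, schema_version = 1,
    extra_note = "property-fixture"
  ))
}

# Brute-force gap-scan bout oracle, independent of segment_bouts().
bouts_oracle <- function(licks, pause_ms) {
  if (length(licks) == 0) {
    return(tibble::tibble(start_ms = numeric(), end_ms = numeric(), n_licks = integer()))
  }
  out <- list()
  start <- licks[1]
  prev <- licks[1]
  n <- 1L
  for (t in licks[-1]) {
    if (t - prev >= pause_ms) {
      out[[length(out) + 1]] <- c(start, prev, n)
      start <- t
      n <- 1L
    } else {
      n <- n + 1L
    }
    prev <- t
  }
  out[[length(out) + 1]] <- c(start, prev, n)
  m <- do.call(rbind, out)
  tibble::tibble(start_ms = m[, 1], end_ms = m[, 2], n_licks = as.integer(m[, 3]))
}

# Replay oracle: re-derive operant reward/penalty counts from the raw event
# stream of a fixed/progressive-ratio log. thresholds = tick costs per
# successive reinforcer (last element recycled).
replay_wheel_counts <- function(log, thresholds) {
  active_dir <- as.integer(log_meta(log)$active_direction)
  act <- 0L
  inact <- 0L
  rew <- 0L
  pen <- 0L
  for (i in seq_len(nrow(log))) {
    if (log$code[i] != "rotation_tick") next
    thr <- thresholds[min(rew + 1L, length(thresholds))]
    if (log$value[i] == active_dir) {
      act <- act + 1L
      if (act >= thr) {
        rew <- rew + 1L
        act <- 0L
      }
    } else {
      inact <- inact + 1L
      if (inact >= thr) {
        pen <- pen + 1L
        inact <- 0L
      }
    }
  }
  list(rewards = rew, penalties = pen)
}

# Replay oracle for the optogenetic tasks: walk the event stream, counting
# active ticks only while counting is enabled (outside stimulation for the
# positive task, during stimulation for the negative task).
replay_opto_counts <- function(log, negative) {
  active_dir <- as.integer(log_meta(log)$active_direction)
  thr <- round(
    as.numeric(log_meta(log)$fixed_ratio_turns) *
      as.numeric(log_meta(log)$ticks_per_rotation)
  )
  laser_on <- FALSE
  act <- 0L
  earned <- 0L
  for (i in seq_len(nrow(log))) {
    code <- log$code[i]
    if (code == "laser_on") laser_on <- TRUE
    if (code == "laser_off") laser_on <- FALSE
    if (code != "rotation_tick" || log$value[i] != active_dir) next
    counting <- if (negative) laser_on else !laser_on
    if (counting) {
      act <- act + 1L
      if (act >= thr) {
        earned <- earned + 1L
        act <- 0L
      }
    }
  }
  earned
}

fixture_log_path <- function() {
  testthat::test_path("fixture-multispout-5trial.csv")
}
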
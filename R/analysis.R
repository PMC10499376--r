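#' Inter-lick intervals
#'
#' Successive differences of lick times. For trial-based logs the
#' differences are taken within trials only (the spout is retracted between
#' trials, so across-trial gaps are not licking microstructure).
#'
#' @param log A `session_log`.
#' @return Tibble with `trial_index` (`NA` for non-trial tasks) and `ili_ms`.
#' @export
inter_lick_intervals <- function(log) {
  licks <- log[log$code == "lick", , drop = FALSE]
  if (nrow(licks) < 2) {
    return(tibble::tibble(trial_index = integer(), ili_ms = integer()))
  }
  if (any(log$code == "trial_start")) {
    tt <- trial_windows(log)
    idx <- findInterval(licks$time_ms, tt$start_ms)
    in_trial <- idx >= 1 & licks$time_ms <= tt$end_ms[pmax(idx, 1)]
    licks <- licks[in_trial, , drop = FALSE]
    trial <- tt$trial_index[idx[in_trial]]
    dplyr::tibble(trial_index = trial, time_ms = licks$time_ms) |>
      dplyr::group_by(.data$trial_index) |>
      dplyr::reframe(ili_ms = diff(.data$time_ms))
  } else {
    tibble::tibble(trial_index = NA_integer_, ili_ms = diff(licks$time_ms))
  }
}

# trial_start/trial_end windows of a trial-based log.
trial_windows <- function(log) {
  s <- log[log$code == "trial_start", , drop = FALSE]
  e <- log[log$code == "trial_end", , drop = FALSE]
  if (nrow(s) == 0) stop("log contains no trials")
  stopifnot(nrow(s) == nrow(e))
  tibble::tibble(
    trial_index = s$value, start_ms = s$time_ms, end_ms = e$time_ms
  )
}

#' Segment licks into bouts
#'
#' Mice lick in discrete bouts; a pause of at least `pause_ms` between
#' consecutive licks closes a bout. Every lick belongs to exactly one bout.
#'
#' @param lick_times Sorted numeric vector of lick times (ms).
#' @param pause_ms Bout-closing pause criterion (default 1000 ms).
#' @return Tibble with `start_ms`, `end_ms`, `n_licks`, one row per bout,
#'   ordered and non-overlapping.
#' @export
segment_bouts <- function(lick_times, pause_ms = 1000) {
  if (is.unsorted(lick_times)) stop("lick_times must be sorted")
  if (length(lick_times) == 0) {
    return(tibble::tibble(start_ms = numeric(), end_ms = numeric(), n_licks = integer()))
  }
  new_bout <- c(TRUE, diff(lick_times) >= pause_ms)
  bout_id <- cumsum(new_bout)
  tibble::tibble(t = lick_times, bout = bout_id) |>
    dplyr::group_by(.data$bout) |>
    dplyr::summarise(
      start_ms = min(.data$t), end_ms = max(.data$t), n_licks = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(!"bout")
}

#' Per-trial behavioral record
#'
#' One row per trial of a trial-based log: solution and spout identity, lick
#' count, latency from the spout extension command to the first lick
#' (`NA` on lickless trials), and the time of the last lick relative to
#' access onset.
#'
#' @param log A trial-based `session_log` (spout training or multi-spout).
#' @return Tibble with `trial_index`, `solution_index`, `spout_index`,
#'   `n_licks`, `latency_first_lick_ms`, `last_lick_ms`.
#' @export
trial_table <- function(log) {
  tw <- trial_windows(log)
  ext <- log[log$code == "spout_extend_cmd", , drop = FALSE]
  licks <- log[log$code == "lick", , drop = FALSE]
  sols <- meta_int_vec(log, "solution_by_trial")
  spouts <- meta_int_vec(log, "spout_by_trial")
  n <- nrow(tw)
  out <- purrr::map_dfr(seq_len(n), function(k) {
    w0 <- tw$start_ms[k]
    w1 <- tw$end_ms[k]
    ext_t <- ext$time_ms[ext$time_ms >= w0 & ext$time_ms <= w1][1]
    lt <- licks$time_ms[licks$time_ms >= w0 & licks$time_ms <= w1]
    tibble::tibble(
      trial_index = tw$trial_index[k],
      solution_index = if (is.null(sols)) NA_integer_ else sols[k],
      spout_index = if (is.null(spouts)) NA_integer_ else spouts[k],
      n_licks = length(lt),
      latency_first_lick_ms = if (length(lt) > 0) lt[1] - ext_t else NA_real_,
      last_lick_ms = if (length(lt) > 0) lt[length(lt)] - ext_t else NA_real_
    )
  })
  out
}

#' Per-solution summary across counterbalanced sessions
#'
#' Aggregates trial records by solution, not by spout: metrics are computed
#' per session and then averaged across sessions, matching the analysis of a
#' spout-counterbalanced session cycle.
#'
#' @param trials Trial records from [trial_table()], stacked over sessions
#'   with a `session` column (a single session without one is accepted). If
#'   `solution_index` is absent or all-`NA` it is recovered from
#'   `spout_index` via `counterbalance`.
#' @param counterbalance Optional [counterbalance_spouts()] table for
#'   recovering solution identity from spout identity.
#' @return Tibble with one row per solution: `mean_licks_per_trial`,
#'   `mean_latency_ms` (lick trials only), `prop_trials_with_lick`,
#'   `n_sessions`.
#' @export
summarize_by_solution <- function(trials, counterbalance = NULL) {
  if (!"session" %in% names(trials)) trials$session <- 1L
  if ((!"solution_index" %in% names(trials) || all(is.na(trials$solution_index))) &&
    !is.null(counterbalance)) {
    trials$solution_index <- NULL
    trials <- dplyr::left_join(
      trials, counterbalance,
      by = c("session", "spout_index")
    )
  }
  per_session <- trials |>
    dplyr::group_by(.data$session, .data$solution_index) |>
    dplyr::summarise(
      mean_licks_per_trial = mean(.data$n_licks),
      mean_latency_ms = if (any(.data$n_licks > 0)) {
        mean(.data$latency_first_lick_ms[.data$n_licks > 0])
      } else {
        NA_real_
      },
      prop_trials_with_lick = mean(.data$n_licks > 0),
      .groups = "drop"
    )
  per_session |>
    dplyr::group_by(.data$solution_index) |>
    dplyr::summarise(
      mean_licks_per_trial = mean(.data$mean_licks_per_trial),
      mean_latency_ms = mean(.data$mean_latency_ms, na.rm = TRUE),
      prop_trials_with_lick = mean(.data$prop_trials_with_lick),
      n_sessions = dplyr::n(),
      .groups = "drop"
    )
}

#' Mean licks per trial in trial bins
#'
#' Bins trials in session order (default 10 trials per bin) and reports the
#' mean lick count per bin, optionally split by solution -- the
#' within-session satiation profile.
#'
#' @param trials Trial records from [trial_table()].
#' @param bin Trials per bin.
#' @param by_solution Split bins by solution identity?
#' @return Tibble with `bin` (1-based), optionally `solution_index`, and
#'   `mean_licks`.
#' @export
binned_trial_licks <- function(trials, bin = 10L, by_solution = FALSE) {
  trials$bin <- trials$trial_index %/% bin + 1L
  groups <- if (by_solution) c("bin", "solution_index") else "bin"
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(mean_licks = mean(.data$n_licks), .groups = "drop")
}

#' Peri-access lick-rate curve
#'
#' Histogram of lick times relative to access onset (the spout extension
#' command), expressed as a rate in Hz, per solution.
#'
#' @param log A trial-based `session_log`.
#' @param bin_ms Histogram bin width (ms).
#' @param window_ms Extent of the curve after access onset; defaults to the
#'   session's access period length.
#' @return Tibble with `solution_index`, `bin_start_ms`, `lick_rate_hz`.
#' @export
binned_lick_rate <- function(log, bin_ms = 250, window_ms = NULL) {
  if (is.null(window_ms)) window_ms <- meta_num(log, "access_ms", 3000)
  tw <- trial_windows(log)
  licks <- log[log$code == "lick", , drop = FALSE]
  sols <- meta_int_vec(log, "solution_by_trial")
  if (is.null(sols)) sols <- rep(0L, nrow(tw))
  breaks <- seq(0, window_ms, by = bin_ms)
  grid <- tidyr::expand_grid(
    solution_index = sort(unique(sols)),
    bin_start_ms = breaks[-length(breaks)]
  )
  idx <- findInterval(licks$time_ms, tw$start_ms)
  ok <- idx >= 1 & licks$time_ms <= tw$end_ms[pmax(idx, 1)]
  rel <- licks$time_ms[ok] - tw$start_ms[idx[ok]]
  sol_of_lick <- sols[idx[ok]]
  counts <- tibble::tibble(
    solution_index = sol_of_lick,
    bin_start_ms = breaks[pmin(findInterval(rel, breaks), length(breaks) - 1L)]
  ) |>
    dplyr::count(.data$solution_index, .data$bin_start_ms)
  n_trials_per_sol <- as.data.frame(table(solution_index = sols))
  n_trials_per_sol$solution_index <- as.integer(as.character(n_trials_per_sol$solution_index))
  grid |>
    dplyr::left_join(counts, by = c("solution_index", "bin_start_ms")) |>
    dplyr::left_join(n_trials_per_sol, by = "solution_index") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      lick_rate_hz = .data$n / (.data$Freq * bin_ms / 1000)
    ) |>
    dplyr::select("solution_index", "bin_start_ms", "lick_rate_hz")
}

#' Wheel rotation summary
#'
#' Cumulative signed position over the session (positive = active
#' direction), terminal position, and total ticks in each direction.
#'
#' @param log A `session_log` from a wheel task.
#' @return List with `position` (tibble `time_ms`, `position_ticks`, signed
#'   in units of active-direction ticks) and `totals` (one-row tibble with
#'   `terminal_position_ticks`, `total_active_ticks`,
#'   `total_inactive_ticks`).
#' @export
wheel_summary <- function(log) {
  active_dir <- meta_num(log, "active_direction", 1)
  ticks <- log[log$code == "rotation_tick", , drop = FALSE]
  signed <- ticks$value * active_dir # +1 = active
  pos <- cumsum(signed)
  list(
    position = tibble::tibble(
      time_ms = ticks$time_ms,
      position_ticks = as.integer(pos)
    ),
    totals = tibble::tibble(
      terminal_position_ticks = if (length(pos)) as.integer(pos[length(pos)]) else 0L,
      total_active_ticks = sum(signed == 1),
      total_inactive_ticks = sum(signed == -1)
    )
  )
}

#' Progressive-ratio breakpoint
#'
#' Cost (in wheel turns) of the last completed ratio: the schedule entry of
#' the final earned reinforcer, 0 if none was earned. Reinforcers are
#' counted as spout extensions (each reward extends the spout once).
#'
#' @param log A `session_log` from a progressive-ratio session.
#' @return One-row tibble with `n_reinforcers` and `breakpoint`.
#' @export
breakpoint <- function(log) {
  kind <- log_meta(log)$pr_kind
  n <- sum(log$code == "spout_extend_cmd")
  bp <- if (n > 0) ratio_schedule(kind, n)$cost[n] else 0
  tibble::tibble(n_reinforcers = as.integer(n), breakpoint = bp)
}

#' Time in the stimulation-paired zone
#'
#' Dwell time per wheel zone from the `zone_enter` event stream; paired and
#' unpaired dwell always sum to the session duration.
#'
#' @param log A `session_log` from a wheel-time-preference session.
#' @return One-row tibble with `paired_s`, `unpaired_s`, `total_s`.
#' @export
wtp_dwell <- function(log) {
  z <- log[log$code == "zone_enter", , drop = FALSE]
  end_ms <- log$time_ms[log$code == "session_end"]
  if (nrow(z) == 0) stop("log contains no zone_enter events")
  bounds <- c(z$time_ms, end_ms)
  span <- diff(bounds)
  paired_ms <- sum(span[z$value == 0L])
  unpaired_ms <- sum(span[z$value == 1L])
  tibble::tibble(
    paired_s = paired_ms / 1000,
    unpaired_s = unpaired_ms / 1000,
    total_s = (paired_ms + unpaired_ms) / 1000
  )
}

#' Optogenetic response counts
#'
#' Stimulations (positive reinforcement: laser onsets) or pauses (negative
#' reinforcement: laser offsets) earned, plus tick counts in each direction.
#'
#' @param log A `session_log` from an optogenetic session.
#' @return One-row tibble with `n_events` (stimulations or pauses),
#'   `n_laser_on`, `n_laser_off`, `active_ticks`, `inactive_ticks`.
#' @export
opto_counts <- function(log) {
  task <- log_meta(log)$task_kind
  n_on <- sum(log$code == "laser_on")
  n_off <- sum(log$code == "laser_off")
  n_events <- if (identical(task, "opto_negative")) n_off else n_on
  w <- wheel_summary(log)$totals
  tibble::tibble(
    n_events = as.integer(n_events),
    n_laser_on = as.integer(n_on), n_laser_off = as.integer(n_off),
    active_ticks = w$total_active_ticks, inactive_ticks = w$total_inactive_ticks
  )
}

#' Within-subject z-scores across conditions
#'
#' Standardizes a value across conditions separately for each subject (mean
#' 0, SD 1 over that subject's conditions). Subjects with zero variance get
#' all-zero scores and are flagged.
#'
#' @param data Data frame with one row per subject x condition.
#' @param subject,condition,value Column names (strings) of the subject
#'   identifier, condition, and value to standardize.
#' @return `data` with added `z` and logical `constant` columns.
#' @export
zscore_across_conditions <- function(data, subject = "subject",
                                     condition = "condition", value = "value") {
  data |>
    dplyr::group_by(.data[[subject]]) |>
    dplyr::mutate(
      constant = stats::sd(.data[[value]]) == 0 || dplyr::n() < 2,
      z = dplyr::if_else(
        .data$constant,
        0,
        (.data[[value]] - mean(.data[[value]])) / stats::sd(.data[[value]])
      )
    ) |>
    dplyr::ungroup()
}
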
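#' Lick raster for a trial-based session
#'
#' One row per trial, one tick per lick, time relative to access onset.
#'
#' @param log A trial-based `session_log`.
#' @return A ggplot object.
#' @export
plot_lick_raster <- function(log) {
  tw <- trial_windows(log)
  licks <- log[log$code == "lick", , drop = FALSE]
  sols <- meta_int_vec(log, "solution_by_trial")
  idx <- findInterval(licks$time_ms, tw$start_ms)
  ok <- idx >= 1 & licks$time_ms <= tw$end_ms[pmax(idx, 1)]
  df <- tibble::tibble(
    trial = tw$trial_index[idx[ok]],
    rel_ms = licks$time_ms[ok] - tw$start_ms[idx[ok]],
    solution = factor(if (is.null(sols)) 0L else sols[idx[ok]])
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rel_ms / 1000, y = .data$trial, colour = .data$solution
  )) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(
      x = "time from access onset (s)", y = "trial",
      colour = "solution"
    ) +
    ggplot2::theme_minimal()
}

#' Cumulative wheel position over a session
#'
#' Signed cumulative encoder position (positive = active direction).
#'
#' @param log A `session_log` from a wheel task.
#' @return A ggplot object.
#' @export
plot_cumulative_position <- function(log) {
  pos <- wheel_summary(log)$position
  ggplot2::ggplot(pos, ggplot2::aes(
    x = .data$time_ms / 60000,
    y = .data$position_ticks / meta_num(log, "ticks_per_rotation", 64)
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "cumulative position (rotations)") +
    ggplot2::theme_minimal()
}

#' Mean licks per trial by solution
#'
#' @param solution_summary Output of [summarize_by_solution()].
#' @return A ggplot object.
#' @export
plot_licks_by_solution <- function(solution_summary) {
  ggplot2::ggplot(solution_summary, ggplot2::aes(
    x = factor(.data$solution_index), y = .data$mean_licks_per_trial
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "solution", y = "mean licks / trial") +
    ggplot2::theme_minimal()
}

#' Trial-averaged peri-event trace, by solution when annotated
#'
#' @param object A `peth`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peth <- function(object, ...) {
  long <- tidy.peth(object)
  if ("solution_index" %in% names(long)) {
    df <- long |>
      dplyr::group_by(.data$solution_index, .data$time_s) |>
      dplyr::summarise(z = mean(.data$z), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$time_s, y = .data$z, colour = factor(.data$solution_index)
    )) +
      ggplot2::labs(colour = "solution")
  } else {
    df <- long |>
      dplyr::group_by(.data$time_s) |>
      dplyr::summarise(z = mean(.data$z), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$z))
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from access onset (s)", y = "z-score") +
    ggplot2::theme_minimal()
}
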
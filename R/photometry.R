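#' Synthesize a two-channel photometry trace for a session
#'
#' Generates a sensor channel (465 nm analog) as slow polynomial drift plus
#' per-trial double-exponential transients aligned to access onsets plus
#' white noise, and a control channel (405 nm analog) as drift plus noise
#' only. Transient amplitude for a trial is
#' `transient_amp[solution] + lick_coupling * n_licks`, so both solution
#' value and consumption magnitude can be encoded.
#'
#' @param log A trial-based `session_log` (access onsets are the
#'   `spout_extend_cmd` events).
#' @param transient_amp Numeric vector of per-solution transient amplitudes
#'   (z-units before normalization), indexed by solution 0..k-1.
#' @param lick_coupling Additional amplitude per lick in the trial.
#' @param drift_coeffs Cubic drift coefficients (intercept, linear,
#'   quadratic, cubic) over normalized session time in `[0, 1]`.
#' @param tau_rise_s,tau_decay_s Transient kinetics (s).
#' @param noise_sd White-noise standard deviation.
#' @param fs_hz Native sampling rate (Hz).
#' @param seed Integer seed.
#' @return A `photo_trace` tibble with `time_s`, `ctrl`, `sig`; attributes
#'   `fs_hz` and `truth` (per-trial onsets, solutions, lick counts and
#'   generated amplitudes, for validation).
#' @export
synth_trace <- function(log, transient_amp = c(0.2, 0.5, 1, 1.5, 2),
                        lick_coupling = 0, drift_coeffs = c(2, -0.8, 0.3, -0.1),
                        tau_rise_s = 0.2, tau_decay_s = 1.2,
                        noise_sd = 0.1, fs_hz = 100, seed = 1L) {
  set.seed(as.integer(seed))
  dur_s <- max(log$time_ms) / 1000
  time_s <- seq(0, dur_s, by = 1 / fs_hz)
  u <- time_s / dur_s
  drift <- drift_coeffs[1] + drift_coeffs[2] * u + drift_coeffs[3] * u^2 +
    drift_coeffs[4] * u^3
  tw <- trial_windows(log)
  ext <- log[log$code == "spout_extend_cmd", , drop = FALSE]
  onsets_s <- ext$time_ms / 1000
  sols <- meta_int_vec(log, "solution_by_trial")
  if (is.null(sols)) sols <- rep(0L, length(onsets_s))
  licks <- log$time_ms[log$code == "lick"]
  n_licks <- vapply(seq_len(nrow(tw)), function(k) {
    sum(licks >= tw$start_ms[k] & licks <= tw$end_ms[k])
  }, integer(1))
  amps <- transient_amp[sols + 1L] + lick_coupling * n_licks
  # double-exponential kernel, peak-normalized
  kern <- function(dt) {
    k <- exp(-dt / tau_decay_s) - exp(-dt / tau_rise_s)
    tpk <- log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
      (tau_decay_s - tau_rise_s)
    k / (exp(-tpk / tau_decay_s) - exp(-tpk / tau_rise_s))
  }
  transients <- numeric(length(time_s))
  horizon_s <- tau_decay_s * 8
  for (k in seq_along(onsets_s)) {
    if (amps[k] == 0) next
    i0 <- findInterval(onsets_s[k], time_s) + 1L
    i1 <- min(length(time_s), findInterval(onsets_s[k] + horizon_s, time_s))
    if (i0 > i1) next
    dt <- time_s[i0:i1] - onsets_s[k]
    transients[i0:i1] <- transients[i0:i1] + amps[k] * kern(dt)
  }
  sig <- drift + transients + stats::rnorm(length(time_s), sd = noise_sd)
  ctrl <- drift + stats::rnorm(length(time_s), sd = noise_sd)
  structure(
    tibble::tibble(time_s = time_s, ctrl = ctrl, sig = sig),
    fs_hz = fs_hz,
    truth = tibble::tibble(
      trial_index = tw$trial_index, onset_s = onsets_s,
      solution_index = sols, n_licks = n_licks, amp = amps
    ),
    class = c("photo_trace", class(tibble::tibble()))
  )
}

keep_trace_attrs <- function(new, old) {
  structure(new,
    fs_hz = attr(old, "fs_hz", exact = TRUE),
    truth = attr(old, "truth", exact = TRUE),
    class = c("photo_trace", class(tibble::tibble()))
  )
}

#' Remove slow drift by cubic subtraction
#'
#' Fits a third-degree polynomial over the full session to each channel
#' independently by least squares and subtracts it -- the standard
#' correction for slow fluorescence decay.
#'
#' @param trace A `photo_trace`.
#' @return A `photo_trace` with detrended channels.
#' @export
detrend <- function(trace) {
  res <- function(y) {
    stats::residuals(stats::lm(y ~ stats::poly(trace$time_s, 3, raw = TRUE)))
  }
  keep_trace_attrs(
    tibble::tibble(
      time_s = trace$time_s,
      ctrl = as.numeric(res(trace$ctrl)),
      sig = as.numeric(res(trace$sig))
    ),
    trace
  )
}

#' Session-wide z-scoring
#'
#' Normalizes each channel by the mean and standard deviation of the entire
#' session. A constant channel (zero SD) is an error.
#'
#' @param trace A `photo_trace`.
#' @return A `photo_trace` with mean-0, SD-1 channels.
#' @export
zscore_session <- function(trace) {
  z <- function(y) {
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) stop("cannot z-score a constant channel")
    (y - mean(y)) / s
  }
  keep_trace_attrs(
    tibble::tibble(
      time_s = trace$time_s, ctrl = z(trace$ctrl), sig = z(trace$sig)
    ),
    trace
  )
}

#' Peri-event time histogram
#'
#' Aligns a channel to event onsets, resamples each row onto a 20
#' samples-per-second grid by linear interpolation, and shifts each row by
#' its mean over the 3 s (or `baseline_s`) preceding onset so the baseline
#' window has mean zero.
#'
#' @param trace A `photo_trace` (normally detrended and z-scored).
#' @param event_times_s Event (access onset) times in seconds.
#' @param pre_s,post_s Window extent before/after onset (s).
#' @param channel `"sig"` or `"ctrl"`.
#' @param out_hz Output sampling rate; 20 samples/s.
#' @param baseline_s Length of the pre-onset baseline window used for the
#'   shift; defaults to `min(pre_s, 3)`.
#' @param annotations Optional tibble of per-trial annotations (one row per
#'   event, e.g. solution and lick count).
#' @return A `peth` object: list with `z` (trials x timepoints matrix),
#'   `time_s` (grid), `window`, and `trials` (annotations).
#' @export
build_peth <- function(trace, event_times_s, pre_s = 3, post_s = 5,
                       channel = c("sig", "ctrl"), out_hz = 20,
                       baseline_s = NULL, annotations = NULL) {
  channel <- match.arg(channel)
  if (is.null(baseline_s)) baseline_s <- min(pre_s, 3)
  grid <- seq(-pre_s, post_s, by = 1 / out_hz)
  y <- trace[[channel]]
  rows <- lapply(event_times_s, function(t0) {
    stats::approx(trace$time_s, y, xout = t0 + grid, rule = 2)$y
  })
  z <- do.call(rbind, rows)
  base_idx <- grid >= -baseline_s & grid < 0
  if (any(base_idx)) {
    z <- z - rowMeans(z[, base_idx, drop = FALSE])
  }
  trials <- tibble::tibble(
    trial = seq_along(event_times_s) - 1L, onset_s = event_times_s
  )
  if (!is.null(annotations)) trials <- dplyr::bind_cols(trials, annotations)
  structure(
    list(z = z, time_s = grid, window = c(pre_s = pre_s, post_s = post_s), trials = trials),
    class = "peth"
  )
}

#' @export
print.peth <- function(x, ...) {
  cat(
    "<peth> ", nrow(x$z), " trials x ", ncol(x$z), " timepoints, window [",
    -x$window[["pre_s"]], ", ", x$window[["post_s"]], "] s @ ",
    round(1 / diff(x$time_s[1:2])), " Hz\n",
    sep = ""
  )
  invisible(x)
}

#' Long-format view of a peri-event time histogram
#'
#' @param x A `peth`.
#' @param ... Unused.
#' @return Tibble with `trial`, `time_s`, `z`, plus any per-trial
#'   annotations.
#' @export
tidy.peth <- function(x, ...) {
  long <- tidyr::expand_grid(
    trial = x$trials$trial,
    time_s = x$time_s
  )
  long$z <- as.vector(t(x$z))
  dplyr::left_join(long, x$trials, by = "trial")
}

#' Per-trial summaries of the access-period signal
#'
#' The average and peak signal during the access period `[0, access_s]` of
#' each trial of a PETH.
#'
#' @param peth A `peth`.
#' @param access_s Access period length (s).
#' @return Tibble with `trial`, `mean_z`, `peak_z`, plus the PETH's per-trial
#'   annotations.
#' @export
access_summary <- function(peth, access_s = 3) {
  idx <- peth$time_s >= 0 & peth$time_s <= access_s
  out <- tibble::tibble(
    trial = peth$trials$trial,
    mean_z = rowMeans(peth$z[, idx, drop = FALSE]),
    peak_z = apply(peth$z[, idx, drop = FALSE], 1, max)
  )
  dplyr::left_join(out, peth$trials, by = "trial")
}

#' Correlation between access-period signal and licking
#'
#' Pearson product-moment correlation between a per-trial signal summary
#' (e.g. `mean_z`) and the per-trial lick count, with a two-sided test.
#'
#' @param data Data frame with the two per-trial columns.
#' @param signal,behavior Column names (strings).
#' @return One-row tibble with `r`, `p_value`, `n`, `conf_low`, `conf_high`.
#' @export
behavior_correlation <- function(data, signal = "mean_z", behavior = "n_licks") {
  x <- data[[signal]]
  y <- data[[behavior]]
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x),
    conf_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
    conf_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_
  )
}

#' Full photometry processing chain for one session
#'
#' Runs the fixed pipeline detrend -> session z-score -> PETH (20
#' samples/s, baseline-shifted on the 3 s before onset) -> access-period
#' summary -> lick correlation, on a trace aligned to a session log.
#'
#' @param trace A raw `photo_trace`.
#' @param log The `session_log` the trace is aligned to.
#' @param pre_s,post_s PETH window (s).
#' @param channel Channel to process.
#' @return List with `trace` (processed), `peth`, `summary` (per-trial
#'   access summaries), and `correlation`.
#' @export
process_photometry <- function(trace, log, pre_s = 3, post_s = 5,
                               channel = "sig") {
  proc <- zscore_session(detrend(trace))
  tw <- trial_windows(log)
  ext <- log[log$code == "spout_extend_cmd", , drop = FALSE]
  sols <- meta_int_vec(log, "solution_by_trial")
  licks <- log$time_ms[log$code == "lick"]
  n_licks <- vapply(seq_len(nrow(tw)), function(k) {
    sum(licks >= tw$start_ms[k] & licks <= tw$end_ms[k])
  }, integer(1))
  ann <- tibble::tibble(
    solution_index = if (is.null(sols)) rep(0L, nrow(tw)) else sols,
    n_licks = n_licks
  )
  peth <- build_peth(proc, ext$time_ms / 1000,
    pre_s = pre_s, post_s = post_s,
    channel = channel, annotations = ann
  )
  acc <- access_summary(peth, access_s = meta_num(log, "access_ms", 3000) / 1000)
  corr <- behavior_correlation(acc)
  list(trace = proc, peth = peth, summary = acc, correlation = corr)
}
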
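#' Task kinds known to the engine
#' @return Character vector of task identifiers.
#' @export
task_kinds <- function() {
  c(
    "free_access", "spout_training", "operant_fr", "operant_pr",
    "opto_positive", "opto_negative", "wtp", "multispout"
  )
}

#' Build a session configuration
#'
#' Assembles the complete parameterization of one task session. Defaults per
#' task follow the platform's training procedures: a 10 min free-access
#' session; 60 spout-training trials with 5 s access and 20-40 s ITIs; 30 min
#' fixed-ratio sessions at 1/2 turn with 3 s access; progressive ratio capped
#' at 1 hr or 15 min without a reinforcer; 20 min optogenetic sessions with
#' 1 s stimulations (positive) or 3 s pauses of continuous stimulation
#' (negative); a 20 min wheel place-preference session with 5/10 kHz zone
#' tones; and 100 multi-spout trials of 3 s access with 5-10 s ITIs. Reward
#' delivery is five ~1.5 uL solenoid pulses at a 200 ms inter-pulse interval;
#' the wheel encoder resolves 64 positions per rotation.
#'
#' @param task_kind One of [task_kinds()].
#' @param ... Named overrides of any default field.
#' @param seed Integer seed driving all randomness of the session.
#' @return A `session_config` list.
#' @export
session_config <- function(task_kind, ..., seed = 1L) {
  task_kind <- match.arg(task_kind, task_kinds())
  base <- list(
    task_kind = task_kind,
    duration_ms = 1800000L,
    n_trials = 0L,
    fixed_ratio_turns = 0.5,
    access_ms = 3000L,
    pulses_per_reward = 5L,
    inter_pulse_ms = 200L,
    pulse_volume_ul = 1.5,
    iti_lo_ms = 5000L,
    iti_hi_ms = 10000L,
    tone_hz = 5000L,
    tone2_hz = 10000L,
    stim_ms = 1000L,
    pause_ms = 3000L,
    laser_hz = 20L,
    ticks_per_rotation = 64L,
    pr_kind = "semilog",
    pr_timeout_ms = 900000L,
    active_direction = 1L,
    n_solutions = 5L,
    seed = as.integer(seed)
  )
  task_defaults <- switch(task_kind,
    free_access = list(duration_ms = 600000L),
    spout_training = list(
      n_trials = 60L, access_ms = 5000L,
      iti_lo_ms = 20000L, iti_hi_ms = 40000L
    ),
    operant_fr = list(duration_ms = 1800000L),
    operant_pr = list(duration_ms = 3600000L),
    opto_positive = list(duration_ms = 1200000L),
    opto_negative = list(duration_ms = 1200000L, laser_hz = 10L),
    wtp = list(duration_ms = 1200000L),
    multispout = list(n_trials = 100L, access_ms = 3000L)
  )
  cfg <- utils::modifyList(base, task_defaults)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown session_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, dots)
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
  structure(cfg, class = "session_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$duration_ms > 0, cfg$access_ms > 0, cfg$inter_pulse_ms > 0,
    cfg$stim_ms > 0, cfg$pause_ms > 0,
    cfg$fixed_ratio_turns > 0,
    cfg$ticks_per_rotation >= 2, cfg$ticks_per_rotation %% 2 == 0,
    cfg$iti_lo_ms <= cfg$iti_hi_ms,
    cfg$active_direction %in% c(-1L, 1L),
    cfg$pr_kind %in% c("semilog", "linear")
  )
  invisible(cfg)
}

#' Stable digest of a configuration
#'
#' A short hexadecimal checksum of the canonical `key=value` serialization,
#' recorded in every log header so a log can be matched to the configuration
#' that produced it.
#'
#' @param cfg A `session_config` or any named list of scalars.
#' @return 8-character hex string.
#' @export
config_digest <- function(cfg) {
  keys <- sort(names(cfg))
  s <- paste(keys, vapply(cfg[keys], function(x) paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";"
  )
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key=value`; blank lines and `#` comments ignored.
#' Values that parse as numbers are converted; comma-separated numeric lists
#' become numeric vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad) > 0) stop("malformed config line: '", lines[bad[1]], "'")
  vals <- lapply(kv, function(x) {
    parts <- trimws(strsplit(x[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else x[2]
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), character(1)))
}

#' Write a flat key=value configuration file
#'
#' @param x Named list of scalars or numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  lines <- paste0(
    names(x), "=",
    vapply(x, function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
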
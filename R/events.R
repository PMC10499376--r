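#' Event codes recognized in a session log
#'
#' The closed enumeration of event kinds a session log may contain. The
#' `value` column of a log row is an integer payload whose meaning depends on
#' the code: spout index (0-4) for `lick`, `solenoid_open`,
#' `spout_extend_cmd` and `spout_retract_cmd`; rotation direction (+1/-1) for
#' `rotation_tick`; tone frequency in Hz for `tone_on`; laser pulse frequency
#' in Hz for `laser_on`; zone index (0 = stimulation-paired, 1 = unpaired)
#' for `zone_enter`; trial index for `trial_start`/`trial_end`; 0 when
#' unused.
#'
#' @return Character vector of valid event codes.
#' @export
event_codes <- function() {
  c(
    "session_start", "session_end", "trial_start", "trial_end",
    "lick", "solenoid_open", "spout_extend_cmd", "spout_retract_cmd",
    "brake_on", "brake_off", "tone_on", "tone_off",
    "laser_on", "laser_off", "rotation_tick", "zone_enter"
  )
}

#' Schema version of the on-disk log format
#' @keywords internal
LOG_SCHEMA_VERSION <- 1L

# Metadata keys every log must carry.
REQUIRED_META <- c("session_id", "task_kind", "config_digest", "seed", "schema_version")

#' Construct a session log
#'
#' A session log is a tibble of timestamped events (`time_ms`, `code`,
#' `value`) carrying session metadata as an attribute. It is the single
#' interchange format between the task engines and the analysis layer.
#'
#' @param events Data frame with integer `time_ms` (milliseconds from session
#'   start), character `code` (see [event_codes()]) and integer `value`.
#' @param metadata Named list or character vector of session metadata. Must
#'   include `session_id`, `task_kind`, `config_digest`, `seed` and
#'   `schema_version`; any further keys are preserved. All values are stored
#'   as single strings.
#' @param check If `TRUE` (default), run [validate_log()] and error on any
#'   violation.
#' @return A `session_log` tibble.
#' @export
session_log <- function(events, metadata, check = TRUE) {
  stopifnot(is.data.frame(events), all(c("time_ms", "code", "value") %in% names(events)))
  meta <- vapply(metadata, function(x) as.character(x)[1], character(1))
  missing <- setdiff(REQUIRED_META, names(meta))
  if (length(missing) > 0) {
    stop("session metadata is missing required keys: ", paste(missing, collapse = ", "))
  }
  ev <- tibble::tibble(
    time_ms = as.integer(events$time_ms),
    code = as.character(events$code),
    value = as.integer(events$value)
  )
  log <- structure(ev,
    metadata = as.list(meta),
    class = c("session_log", class(tibble::tibble()))
  )
  if (check) {
    v <- validate_log(log)
    if (nrow(v) > 0) {
      stop(
        "invalid session log (", nrow(v), " violation(s)); first: event ",
        v$index[1], ": ", v$rule[1], " - ", v$detail[1]
      )
    }
  }
  log
}

#' Session metadata of a log
#'
#' @param log A `session_log`.
#' @return Named list of single strings.
#' @export
log_meta <- function(log) {
  attr(log, "metadata", exact = TRUE)
}

# Numeric metadata accessor with optional default.
meta_num <- function(log, key, default = NA_real_) {
  m <- log_meta(log)
  if (is.null(m[[key]])) default else as.numeric(m[[key]])
}

# Comma-joined integer metadata accessor (e.g. per-trial solution identity).
meta_int_vec <- function(log, key) {
  m <- log_meta(log)
  if (is.null(m[[key]])) return(NULL)
  as.integer(strsplit(m[[key]], ",", fixed = TRUE)[[1]])
}

#' @export
print.session_log <- function(x, ...) {
  m <- log_meta(x)
  cat(
    "<session_log> task=", m$task_kind, " id=", m$session_id,
    " seed=", m$seed, " events=", nrow(x), "\n",
    sep = ""
  )
  NextMethod()
}

#' Validate a session log
#'
#' Checks every structural invariant of the event-log data model and returns
#' the violations as data, not exceptions: timestamps are non-negative and
#' non-decreasing; codes belong to [event_codes()]; the log opens with
#' exactly one `session_start` at time 0 and closes with exactly one
#' `session_end`; `trial_start`/`trial_end` strictly alternate with
#' consecutive 0-based indices; each of the `tone`/`laser`/`brake` families
#' alternates on/off (an on left open at `session_end` is allowed -- the end
#' of the session terminates it).
#'
#' @param log A `session_log` (or any data frame with the log columns).
#' @return Tibble with one row per violation: `index` (event row), `rule`,
#'   `detail`. Zero rows iff the log is valid.
#' @export
validate_log <- function(log) {
  v <- list()
  bad <- function(index, rule, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(
      index = as.integer(index), rule = rule, detail = detail
    )
  }
  n <- nrow(log)
  t <- log$time_ms
  code <- log$code

  if (n == 0) {
    bad(0L, "nonempty", "log has no events")
    return(dplyr::bind_rows(v))
  }
  neg <- which(t < 0)
  for (i in neg) bad(i, "time_nonnegative", paste0("time_ms ", t[i], " < 0"))
  dec <- which(diff(t) < 0) + 1L
  for (i in dec) {
    bad(i, "time_monotone", paste0("time_ms ", t[i], " < preceding ", t[i - 1]))
  }
  unk <- which(!code %in% event_codes())
  for (i in unk) bad(i, "known_code", paste0("unknown code '", code[i], "'"))

  starts <- which(code == "session_start")
  ends <- which(code == "session_end")
  if (length(starts) != 1 || starts[1] != 1L || t[1] != 0L) {
    bad(1L, "session_start_first", "expected exactly one session_start as first event at time 0")
  }
  if (length(ends) != 1 || ends[1] != n) {
    bad(n, "session_end_last", "expected exactly one session_end as last event")
  }

  # trial pairing: strict alternation, consecutive indices from 0
  tr <- which(code %in% c("trial_start", "trial_end"))
  expect_start <- TRUE
  next_idx <- 0L
  for (i in tr) {
    if (code[i] == "trial_start") {
      if (!expect_start) {
        bad(i, "trial_alternation", "trial_start while previous trial still open")
      }
      if (log$value[i] != next_idx) {
        bad(i, "trial_index", paste0("trial_start index ", log$value[i], ", expected ", next_idx))
      }
      expect_start <- FALSE
    } else {
      if (expect_start) {
        bad(i, "trial_alternation", "trial_end without open trial")
      } else if (log$value[i] != next_idx) {
        bad(i, "trial_index", paste0("trial_end index ", log$value[i], ", expected ", next_idx))
      }
      if (!expect_start) next_idx <- next_idx + 1L
      expect_start <- TRUE
    }
  }
  if (!expect_start) {
    bad(tr[length(tr)], "trial_pairing", "trial_start without trial_end before session_end")
  }

  # on/off alternation per actuator family
  for (fam in c("tone", "laser", "brake")) {
    on_code <- paste0(fam, "_on")
    off_code <- paste0(fam, "_off")
    idx <- which(code %in% c(on_code, off_code))
    state_on <- FALSE
    for (i in idx) {
      if (code[i] == on_code) {
        if (state_on) bad(i, paste0(fam, "_pairing"), paste0(on_code, " while already on"))
        state_on <- TRUE
      } else {
        if (!state_on) bad(i, paste0(fam, "_pairing"), paste0(off_code, " while already off"))
        state_on <- FALSE
      }
    }
    # an open on is terminated by session_end: not a violation
  }
  if (length(v) == 0) {
    return(tibble::tibble(index = integer(), rule = character(), detail = character()))
  }
  dplyr::bind_rows(v)
}

#' Write a session log to a CSV file
#'
#' Serializes a log as UTF-8, LF-newline CSV: `#`-prefixed `key=value`
#' metadata header lines, then a `time_ms,code,value` header, then one row
#' per event. Round-trips bit-exactly through [read_log()].
#'
#' @param log A valid `session_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  v <- validate_log(log)
  if (nrow(v) > 0) {
    stop(
      "refusing to write invalid log (", nrow(v), " violation(s)); first: event ",
      v$index[1], ": ", v$rule[1], " - ", v$detail[1]
    )
  }
  meta <- log_meta(log)
  header <- paste0("# ", names(meta), "=", unlist(meta))
  rows <- paste(log$time_ms, log$code, log$value, sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, "time_ms,code,value", rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a session log from a CSV file
#'
#' Parses the format written by [write_log()]. Malformed rows and unknown
#' event codes raise errors naming the offending line; the parsed log is
#' validated and structural violations (e.g. non-monotone timestamps) also
#' raise.
#'
#' @param path Path to a log CSV file.
#' @return A validated `session_log`.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("log file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta_lines <- sub("^#\\s*", "", lines[is_meta])
  kv <- regmatches(meta_lines, regexpr("=", meta_lines, fixed = TRUE), invert = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(x) if (length(x) == 2) x[2] else ""),
    vapply(kv, `[`, character(1), 1)
  )
  body <- which(!is_meta & nzchar(lines))
  if (length(body) == 0 || lines[body[1]] != "time_ms,code,value") {
    stop("line ", if (length(body)) body[1] else length(lines),
         ": expected header 'time_ms,code,value'")
  }
  data_idx <- body[-1]
  fields <- strsplit(lines[data_idx], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3)) {
    i <- which(nf != 3)[1]
    stop("line ", data_idx[i], ": malformed row (expected 3 fields, got ", nf[i], ")")
  }
  time_ms <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 1)))
  code <- vapply(fields, `[`, character(1), 2)
  value <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  if (anyNA(time_ms) || anyNA(value)) {
    i <- which(is.na(time_ms) | is.na(value))[1]
    stop("line ", data_idx[i], ": non-integer time_ms or value")
  }
  unk <- which(!code %in% event_codes())
  if (length(unk) > 0) {
    stop("line ", data_idx[unk[1]], ": unknown event code '", code[unk[1]], "'")
  }
  session_log(
    tibble::tibble(time_ms = time_ms, code = code, value = value),
    metadata = meta, check = TRUE
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a session log
#'
#' @param x A `session_log`.
#' @param ... Unused.
#' @return One-row tibble with task kind, seed, duration, and event counts.
#' @export
glance.session_log <- function(x, ...) {
  m <- log_meta(x)
  tibble::tibble(
    session_id = m$session_id,
    task_kind = m$task_kind,
    seed = as.integer(m$seed),
    duration_ms = max(x$time_ms),
    n_events = nrow(x),
    n_trials = sum(x$code == "trial_start"),
    n_licks = sum(x$code == "lick"),
    n_solenoid = sum(x$code == "solenoid_open"),
    n_ticks = sum(x$code == "rotation_tick")
  )
}

#' Events of a session log as a plain tibble
#'
#' @param x A `session_log`.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `code`, `value`.
#' @export
tidy.session_log <- function(x, ...) {
  tibble::tibble(time_ms = x$time_ms, code = x$code, value = x$value)
}
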
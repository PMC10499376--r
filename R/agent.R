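#' Virtual-mouse behavioral parameters
#'
#' The agent converts task stimuli into licks and wheel rotations. Licking is
#' a bout-structured renewal process gated on spout availability: bouts
#' initiate at a per-solution Poisson rate (the palatability map), contain a
#' geometric number of licks, and within-bout inter-lick intervals are
#' log-normal (default mean 140 ms, the rhythmic ~7 Hz licking typical of
#' mice). Rotation is a point process of encoder ticks whose direction is a
#' biased coin and whose rate can be modulated by reinforcement and, in the
#' wheel place-preference task, by the stimulation-paired zone.
#'
#' @param ili_mean_ms Mean within-bout inter-lick interval (ms).
#' @param ili_cv Coefficient of variation of the inter-lick interval.
#' @param bout_len_mean Mean licks per bout (geometric, minimum 1).
#' @param bout_rate_hz Bout-initiation rate (Hz) during access, one value per
#'   solution index (recycled if scalar) -- the palatability map.
#' @param rot_rate_ticks_per_s Baseline wheel tick rate (ticks/s).
#' @param active_bias Probability a tick is in the active direction.
#' @param reinforcement_gain Multiplicative change in tick rate after each
#'   reward or stimulation (capped at 10x baseline).
#' @param zone_drift Wheel place-preference drift in `[-1, 1]`: the tick rate
#'   is scaled by `1 - d` while stimulated and `1 + d` otherwise, where
#'   `d = zone_drift * min(laser_hz, 40) / 40`; positive values produce
#'   preference for the paired zone, negative values avoidance, 0
#'   indifference.
#' @param satiation_tau_s Exponential decay constant (s) of the bout
#'   initiation rate across the session; `Inf` disables satiation.
#' @param deterministic_ticks If `TRUE`, tick gaps are exactly
#'   `1000/rate` ms instead of exponential (useful for closed-form checks).
#' @return An `agent_params` list.
#' @export
agent_params <- function(ili_mean_ms = 140, ili_cv = 0.25, bout_len_mean = 6,
                         bout_rate_hz = 0.5, rot_rate_ticks_per_s = 3,
                         active_bias = 0.8, reinforcement_gain = 1,
                         zone_drift = 0, satiation_tau_s = Inf,
                         deterministic_ticks = FALSE) {
  p <- list(
    ili_mean_ms = ili_mean_ms, ili_cv = ili_cv, bout_len_mean = bout_len_mean,
    bout_rate_hz = bout_rate_hz, rot_rate_ticks_per_s = rot_rate_ticks_per_s,
    active_bias = active_bias, reinforcement_gain = reinforcement_gain,
    zone_drift = zone_drift, satiation_tau_s = satiation_tau_s,
    deterministic_ticks = isTRUE(as.logical(deterministic_ticks))
  )
  stopifnot(
    p$ili_mean_ms > 0, p$ili_cv >= 0, p$bout_len_mean >= 1,
    all(p$bout_rate_hz >= 0), p$rot_rate_ticks_per_s >= 0,
    p$active_bias >= 0, p$active_bias <= 1,
    p$reinforcement_gain >= 0,
    p$zone_drift >= -1, p$zone_drift <= 1,
    p$satiation_tau_s > 0
  )
  structure(p, class = "agent_params")
}

#' Named agent presets
#'
#' Documented parameter sets spanning the phenotypes the platform is built to
#' measure: `learner` (reinforcement-sensitive operant responder),
#' `non_responder` (no wheel responding), `indifferent` (symmetric rotation,
#' no zone drift), `preferrer`/`avoider` (strong drift toward/away from the
#' stimulation-paired zone), and `concentration_tracker` (bout-initiation
#' rate increasing with solution index, emulating licking that scales with
#' sucrose concentration).
#'
#' @param name Preset name.
#' @return An `agent_params` list.
#' @export
preset <- function(name) {
  presets <- list(
    learner = agent_params(
      rot_rate_ticks_per_s = 2, active_bias = 0.65,
      reinforcement_gain = 1.15, bout_rate_hz = 0.6
    ),
    non_responder = agent_params(rot_rate_ticks_per_s = 0, bout_rate_hz = 0.3),
    indifferent = agent_params(
      rot_rate_ticks_per_s = 4, active_bias = 0.5, zone_drift = 0
    ),
    preferrer = agent_params(
      rot_rate_ticks_per_s = 4, active_bias = 0.5, zone_drift = 0.9
    ),
    avoider = agent_params(
      rot_rate_ticks_per_s = 4, active_bias = 0.5, zone_drift = -0.9
    ),
    concentration_tracker = agent_params(
      bout_rate_hz = c(0.15, 0.3, 0.5, 0.75, 1.0),
      rot_rate_ticks_per_s = 0
    )
  )
  if (!name %in% names(presets)) {
    stop(
      "unknown preset '", name, "'; available: ",
      paste(names(presets), collapse = ", ")
    )
  }
  presets[[name]]
}

# Bout-initiation rate for a solution index (0-based), recycling scalars.
agent_bout_rate <- function(params, solution = 0L) {
  r <- params$bout_rate_hz
  r[(as.integer(solution) %% length(r)) + 1L]
}

# Log-normal parameters from mean and CV.
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a bout-structured lick train
#'
#' Simulates the agent's licking over one access window `[t0_ms, t1_ms)`
#' using the current RNG stream: bout onsets from an exponential renewal
#' process at the (optionally satiation-decayed) bout rate, bout lengths
#' geometric with mean `bout_len_mean`, within-bout intervals log-normal.
#'
#' @param params An `agent_params`.
#' @param solution Solution index selecting the palatability-map rate.
#' @param t0_ms,t1_ms Window bounds in ms (absolute session time).
#' @param session_t0_ms Session origin for satiation decay.
#' @return Sorted integer vector of lick times in `[t0_ms, t1_ms)`.
#' @export
gen_lick_train <- function(params, solution = 0L, t0_ms, t1_ms,
                           session_t0_ms = 0) {
  base_rate <- agent_bout_rate(params, solution)
  if (base_rate <= 0 || t1_ms <= t0_ms) return(integer(0))
  lp <- lnorm_pars(params$ili_mean_ms, max(params$ili_cv, 1e-9))
  p_geom <- 1 / params$bout_len_mean
  out <- list()
  t <- t0_ms
  repeat {
    rate <- base_rate
    if (is.finite(params$satiation_tau_s)) {
      rate <- base_rate * exp(-((t - session_t0_ms) / 1000) / params$satiation_tau_s)
    }
    if (rate <= 0) break
    gap_ms <- stats::rexp(1, rate) * 1000
    bout_start <- t + gap_ms
    if (bout_start >= t1_ms) break
    n <- 1L + stats::rgeom(1, p_geom)
    ilis <- if (n > 1) stats::rlnorm(n - 1L, lp$meanlog, lp$sdlog) else numeric(0)
    licks <- bout_start + c(0, cumsum(ilis))
    out[[length(out) + 1L]] <- licks[licks < t1_ms]
    t <- licks[length(licks)] # renewal restarts after the bout ends
    if (t >= t1_ms) break
  }
  all_licks <- unlist(out, use.names = FALSE)
  if (length(all_licks) == 0) return(integer(0))
  times <- unique(as.integer(round(all_licks)))
  sort(times[times >= t0_ms & times < t1_ms])
}

#' Advance the agent by one clock step
#'
#' The per-timestep micro interface to the virtual mouse: given the current
#' actuator states, advance `dt_ms` and return the actions taken. Licks are
#' gated on spout availability; rotation is a biased coin over a Poisson
#' tick. The task engines sample the identical processes in event-driven
#' form; this stepwise view is convenient for inspecting the agent in
#' isolation.
#'
#' @param params An `agent_params`.
#' @param state Internal state from the previous step, or `NULL` to start.
#' @param stimuli List of actuator states: `spout_extended` (logical),
#'   `solution` (index), `braked` (logical), `rate_mult` (reinforcement
#'   multiplier, default 1).
#' @param dt_ms Clock step in ms.
#' @return List with `lick` (logical), `dticks` (-1/0/+1), `state`.
#' @export
agent_step <- function(params, state = NULL, stimuli = list(), dt_ms = 1) {
  if (is.null(state)) state <- list(next_lick_in = Inf, bout_left = 0L, t_ms = 0)
  spout <- isTRUE(stimuli$spout_extended)
  braked <- isTRUE(stimuli$braked)
  solution <- if (is.null(stimuli$solution)) 0L else stimuli$solution
  rate_mult <- if (is.null(stimuli$rate_mult)) 1 else stimuli$rate_mult
  lick <- FALSE
  lp <- lnorm_pars(params$ili_mean_ms, max(params$ili_cv, 1e-9))

  if (spout) {
    if (state$bout_left > 0L) {
      state$next_lick_in <- state$next_lick_in - dt_ms
      if (state$next_lick_in <= 0) {
        lick <- TRUE
        state$bout_left <- state$bout_left - 1L
        state$next_lick_in <- if (state$bout_left > 0L) {
          stats::rlnorm(1, lp$meanlog, lp$sdlog)
        } else {
          Inf
        }
      }
    } else {
      rate <- agent_bout_rate(params, solution)
      if (stats::runif(1) < rate * dt_ms / 1000) {
        lick <- TRUE
        n <- 1L + stats::rgeom(1, 1 / params$bout_len_mean)
        state$bout_left <- n - 1L
        state$next_lick_in <- if (state$bout_left > 0L) {
          stats::rlnorm(1, lp$meanlog, lp$sdlog)
        } else {
          Inf
        }
      }
    }
  } else {
    state$bout_left <- 0L
    state$next_lick_in <- Inf
  }

  dticks <- 0L
  if (!braked && params$rot_rate_ticks_per_s > 0) {
    rate <- params$rot_rate_ticks_per_s * rate_mult
    if (stats::runif(1) < rate * dt_ms / 1000) {
      dticks <- if (stats::runif(1) < params$active_bias) 1L else -1L
    }
  }
  state$t_ms <- state$t_ms + dt_ms
  list(lick = lick, dticks = dticks, state = state)
}

#' Read or write agent parameters as a key=value file
#'
#' @param path File path.
#' @return [read_agent()]: an `agent_params`. [write_agent()]: `path`,
#'   invisibly.
#' @export
read_agent <- function(path) {
  kv <- read_config(path)
  known <- names(formals(agent_params))
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0) {
    stop("unknown agent parameter(s): ", paste(unknown, collapse = ", "))
  }
  do.call(agent_params, kv)
}

#' @rdname read_agent
#' @param params An `agent_params`.
#' @export
write_agent <- function(params, path) {
  write_config(unclass(params), path)
}
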
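#' Pseudorandom multi-spout solution sequence
#'
#' Generates the brief-access trial order: within every consecutive block of
#' `block_size` trials each solution appears exactly `per_block` times, in a
#' seeded uniform shuffle (the standard "two presentations of each solution
#' per every 10 trials" schedule is the default geometry). No cross-block
#' constraint is imposed.
#'
#' @param n_trials Total trials; must be divisible by `block_size`.
#' @param n_solutions Number of solutions (indices `0:(n_solutions-1)`).
#' @param block_size Trials per block; must equal `n_solutions * per_block`.
#' @param per_block Presentations of each solution per block.
#' @param seed Integer seed.
#' @return Integer vector of length `n_trials` of 0-based solution indices.
#' @export
schedule_multispout <- function(n_trials = 100L, n_solutions = 5L,
                                block_size = 10L, per_block = 2L, seed = 1L) {
  if (block_size != n_solutions * per_block) {
    stop("block_size (", block_size, ") must equal n_solutions * per_block (",
         n_solutions * per_block, ")")
  }
  if (n_trials %% block_size != 0) {
    stop("n_trials (", n_trials, ") must be divisible by block_size (", block_size, ")")
  }
  set.seed(as.integer(seed))
  n_blocks <- n_trials %/% block_size
  block <- rep(seq_len(n_solutions) - 1L, each = per_block)
  unlist(lapply(seq_len(n_blocks), function(b) sample(block)))
}

#' Latin-square spout-solution counterbalancing
#'
#' Assigns solutions to spouts over `n` sessions such that every
#' (spout, solution) pair occurs exactly once -- a Latin square, sampled as a
#' seeded random row/column permutation of the cyclic square.
#'
#' @param n Number of sessions (= spouts = solutions).
#' @param seed Integer seed.
#' @return Tibble with columns `session` (1..n), `solution_index` and
#'   `spout_index` (0-based), one row per (session, solution).
#' @export
counterbalance_spouts <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  rowp <- sample(n)
  colp <- sample(n)
  # cyclic square L[i, j] = (i + j) mod n, then independent row/col shuffles
  grid <- expand.grid(session = seq_len(n), solution = seq_len(n))
  spout <- (rowp[grid$session] + colp[grid$solution]) %% n
  tibble::tibble(
    session = grid$session,
    solution_index = grid$solution - 1L,
    spout_index = as.integer(spout)
  ) |>
    dplyr::arrange(.data$session, .data$solution_index)
}

#' Sample inter-trial intervals
#'
#' Uniform over the closed integer interval `[lo_ms, hi_ms]`, the schedule
#' used between access periods (5-10 s for multi-spout sessions, 20-40 s for
#' spout training).
#'
#' @param lo_ms,hi_ms Bounds in milliseconds, `lo_ms <= hi_ms`.
#' @param n Number of samples.
#' @return Integer vector of length `n`.
#' @export
sample_iti <- function(lo_ms, hi_ms, n = 1L) {
  if (lo_ms > hi_ms) stop("lo_ms (", lo_ms, ") must be <= hi_ms (", hi_ms, ")")
  lo_ms <- as.integer(lo_ms)
  hi_ms <- as.integer(hi_ms)
  as.integer(lo_ms + floor(stats::runif(n) * (hi_ms - lo_ms + 1L)))
}

# Printed semilogarithmic cost prefix (wheel turns per reinforcer).
SEMILOG_PREFIX <- c(0.25, 0.5, 0.81, 1.21, 1.71, 2.3, 3.1, 4.1)

#' Progressive-ratio cost schedule
#'
#' Wheel-turn cost of each successive reinforcer. The `semilog` schedule
#' reproduces the platform's printed prefix `0.25, 0.5, 0.81, 1.21, 1.71,
#' 2.3, 3.1, 4.1` exactly; beyond the eighth term it continues
#' deterministically by the prefix's asymptotic growth ratio,
#' `cost_i = round(cost_{i-1} * 1.32, 2)`. The `linear` schedule is
#' `0.5 * i`.
#'
#' @param kind `"semilog"` or `"linear"`.
#' @param n Number of reinforcers (>= 1).
#' @return Tibble with columns `kind`, `reinforcer` (1..n), `cost` (wheel
#'   turns, strictly increasing).
#' @export
ratio_schedule <- function(kind = c("semilog", "linear"), n) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  costs <- if (kind == "linear") {
    0.5 * seq_len(n)
  } else {
    out <- SEMILOG_PREFIX
    while (length(out) < n) {
      out <- c(out, round(out[length(out)] * 1.32, 2))
    }
    out[seq_len(n)]
  }
  tibble::tibble(kind = kind, reinforcer = seq_len(n), cost = costs)
}

#' Full trial plan for a multi-spout session
#'
#' Combines the pseudorandom solution schedule, a solution-to-spout
#' assignment, and sampled inter-trial intervals into the per-trial plan the
#' engine consumes.
#'
#' @param n_trials,n_solutions,block_size,per_block See
#'   [schedule_multispout()].
#' @param spout_map Integer vector mapping solution index to spout index
#'   (position `s + 1` gives the spout for solution `s`), e.g. one session of
#'   [counterbalance_spouts()]. Defaults to the identity map.
#' @param iti_lo_ms,iti_hi_ms Inter-trial interval bounds in ms.
#' @param seed Integer seed.
#' @return Tibble with `trial_index` (0-based), `solution_index`,
#'   `spout_index`, `iti_ms`.
#' @export
trial_plan <- function(n_trials = 100L, n_solutions = 5L, block_size = 10L,
                       per_block = 2L, spout_map = seq_len(n_solutions) - 1L,
                       iti_lo_ms = 5000L, iti_hi_ms = 10000L, seed = 1L) {
  stopifnot(length(spout_map) == n_solutions)
  sol <- schedule_multispout(n_trials, n_solutions, block_size, per_block, seed = seed)
  # solution order consumed the seed stream; ITIs continue from it
  itis <- sample_iti(iti_lo_ms, iti_hi_ms, n = n_trials)
  tibble::tibble(
    trial_index = seq_len(n_trials) - 1L,
    solution_index = as.integer(sol),
    spout_index = as.integer(spout_map[sol + 1L]),
    iti_ms = itis
  )
}
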
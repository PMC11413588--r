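## Metropolis index-copy dynamics and the Monte Carlo Step (MCS) clock.

#' Metropolis acceptance probability
#'
#' The standard Metropolis-Boltzmann rule: downhill or neutral moves
#' (`delta_h <= 0`) are always accepted; uphill moves are accepted with
#' probability `exp(-delta_h / Tm)`, where `Tm` is the domain temperature.
#'
#' @param delta_h energy change(s) of the proposed copy.
#' @param Tm domain temperature, > 0 (default 37, the model's setting).
#' @return acceptance probability in `[0, 1]`, vectorized over `delta_h`.
#' @examples
#' acceptance_probability(0, 37)   # 1
#' acceptance_probability(37, 37)  # exp(-1)
#' @export
acceptance_probability <- function(delta_h, Tm = 37) {
  if (Tm <= 0) stop("Tm must be > 0")
  ifelse(delta_h <= 0, 1, exp(-delta_h / Tm))
}

#' Perform a single index-copy attempt
#'
#' Samples a target voxel uniformly and a source site uniformly among its
#' neighbors (a virtual medium site if outside a fixed-medium lattice). If the
#' labels differ, the energy change is computed and the copy accepted with
#' [acceptance_probability()]; same-label draws count as an attempt and are
#' rejected without an energy evaluation. Uses R's global RNG stream, so
#' `set.seed()` fixes the draw.
#'
#' @param state a `cpm_state`.
#' @return list with elements `state` (updated), `accepted`, `same_label`,
#'   `delta_h` (NA for same-label draws), `source_label` and `target_voxel`
#'   (1-based linear index).
#' @export
attempt_index_copy <- function(state) {
  a <- .state_args(state)
  res <- .cpm_attempt(a$labels, a$ids, a$types, a$volumes, a$targets,
                      .cpp_par(state$params))
  list(state = .absorb_cpp(state, res), accepted = res$accepted,
       same_label = res$same_label, delta_h = res$delta_h,
       source_label = res$source_label, target_voxel = res$target_voxel)
}

#' Advance a state by whole Monte Carlo Steps
#'
#' One MCS performs `attempts_per_mcs` index-copy attempts (default: one per
#' lattice voxel), then — unless the lifecycle flag is off — runs the
#' compartment lifecycle sweep (cell growth, mitosis, ECM secretion, cell
#' death, ECM decay and deletion) in randomized compartment order, and
#' advances the clock by one MCS.
#'
#' @param state a `cpm_state`.
#' @param n number of MCS to run.
#' @param record_events if TRUE, append lifecycle events (mitosis, secretion,
#'   deletions, blocked secretions) to `state$events`.
#' @return the advanced state.
#' @export
run_mcs <- function(state, n = 1, record_events = FALSE) {
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(state)
  p <- unclass(state$params)
  attempts <- p$domain$attempts_per_mcs %||% prod(dim(state$labels))
  if (attempts < 0) stop("attempts_per_mcs must be >= 0")
  a <- .state_args(state)
  res <- .cpm_run(a$labels, a$ids, a$types, a$volumes, a$targets,
                  .cpp_par(state$params), n, as.numeric(attempts),
                  state$mcs, record_events)
  .absorb_cpp(state, res)
}

#' Run a simulation and collect snapshots
#'
#' Convenience driver around [run_mcs()]: advances the state `mcs` steps,
#' storing a snapshot (a full copy of the state) every `snapshot_every` MCS,
#' the initial and final states included.
#'
#' @param state the 0-MCS state, e.g. from [seed_zone()].
#' @param mcs total number of Monte Carlo Steps to run.
#' @param snapshot_every snapshot interval in MCS (default: `mcs`, i.e. only
#'   the initial and final states are kept).
#' @param seed optional integer; if given, `set.seed(seed)` is called first so
#'   the whole trajectory is reproducible.
#' @param record_events passed to [run_mcs()].
#' @param progress if TRUE, print one line per snapshot (MCS, day equivalent,
#'   compartment counts, total energy).
#' @return list with `state` (final), `snapshots` (list of `cpm_state`), and
#'   `metrics` (the [summary_timeseries()] of the snapshots).
#' @export
run_simulation <- function(state, mcs, snapshot_every = NULL, seed = NULL,
                           record_events = TRUE, progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  mcs <- as.integer(mcs)
  snapshot_every <- as.integer(snapshot_every %||% max(mcs, 1L))
  if (snapshot_every < 1) stop("snapshot_every must be >= 1")
  snaps <- list(state)
  done <- 0L
  while (done < mcs) {
    step <- min(snapshot_every, mcs - done)
    state <- run_mcs(state, step, record_events = record_events)
    done <- done + step
    snaps[[length(snaps) + 1L]] <- state
    if (progress) {
      cat(sprintf("MCS %d (day %.2f): %d compartments, H = %.1f\n",
                  state$mcs, day_for_mcs(state$mcs, state$params$clock),
                  nrow(state$comps), total_energy(state)))
    }
  }
  list(state = state, snapshots = snaps, metrics = summary_timeseries(snaps))
}

## ---- simulated-time mapping ----------------------------------------------

#' The simulation clock
#'
#' The calibration between Monte Carlo Steps and culture time: one MCS is 6
#' minutes, 240 MCS are one day, and MCS 0 corresponds to culture day 1 (so
#' MCS 3120 is day 14).
#'
#' @param minutes_per_step minutes of culture time per MCS.
#' @param steps_per_day MCS per culture day.
#' @param day_at_mcs_zero culture day represented by MCS 0.
#' @return a `simulation_clock` list.
#' @export
simulation_clock <- function(minutes_per_step = 6, steps_per_day = 240,
                             day_at_mcs_zero = 1) {
  structure(list(minutes_per_step = minutes_per_step,
                 steps_per_day = steps_per_day,
                 day_at_mcs_zero = day_at_mcs_zero),
            class = "simulation_clock")
}

#' Monte Carlo Step for a culture day
#' @param day culture day (>= the clock's day at MCS 0).
#' @param clock a [simulation_clock()].
#' @return integer MCS; `mcs_for_day(14)` is 3120.
#' @export
mcs_for_day <- function(day, clock = simulation_clock()) {
  if (any(day < clock$day_at_mcs_zero)) {
    stop("day precedes the simulation origin (day ", clock$day_at_mcs_zero, ")")
  }
  as.integer(round((day - clock$day_at_mcs_zero) * clock$steps_per_day))
}

#' Culture day for a Monte Carlo Step
#' @param mcs Monte Carlo Step (>= 0).
#' @param clock a [simulation_clock()].
#' @return culture day; `day_for_mcs(3120)` is 14.
#' @export
day_for_mcs <- function(mcs, clock = simulation_clock()) {
  if (any(mcs < 0)) stop("mcs must be >= 0")
  clock$day_at_mcs_zero + mcs / clock$steps_per_day
}
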
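#' MdMD driver configuration
#'
#' Controls the sprint schedule and acceptance rule of the Maxwell's-demon
#' loop. Sprint lengths adapt multiplicatively: accepted sprints grow the
#' next sprint by `grow_factor` (capped at `max_sprint`), rejected sprints
#' shrink it by `shrink_factor` (floored at `min_sprint`).
#'
#' @param min_sprint shortest sprint, ps (default 0.05 = 50 fs).
#' @param max_sprint longest sprint, ps (default 5).
#' @param initial_sprint first sprint length, ps (default 0.5).
#' @param grow_factor multiplicative growth on acceptance (> 1).
#' @param shrink_factor multiplicative shrink on rejection (in (0, 1)).
#' @param goal_cc target value of the progress variable (default 0.99).
#' @param max_iterations cap on total sprints attempted.
#' @param max_consecutive_rejections stall detector.
#' @param archive_depth k: number of previous archived progress values the
#'   acceptance comparator consults (default 3).
#' @param temperature velocity-reset temperature, K.
#' @param remove_com remove center-of-mass/rotation drift after every
#'   accepted sprint (default TRUE).
#' @param seed master seed; every stochastic draw in the run derives from it.
#' @return object of class `mdmd_config`.
#' @export
mdmd_config <- function(min_sprint = 0.05, max_sprint = 5,
                        initial_sprint = 0.5, grow_factor = 1.5,
                        shrink_factor = 0.5, goal_cc = 0.99,
                        max_iterations = 500,
                        max_consecutive_rejections = 60,
                        archive_depth = 3, temperature = 300,
                        remove_com = TRUE, seed = 1L) {
  if (!(0 < min_sprint && min_sprint <= initial_sprint &&
        initial_sprint <= max_sprint)) {
    stop("need 0 < min_sprint <= initial_sprint <= max_sprint")
  }
  if (!(0 < shrink_factor && shrink_factor < 1 && grow_factor > 1)) {
    stop("need 0 < shrink_factor < 1 < grow_factor")
  }
  if (archive_depth < 1) stop("archive_depth must be >= 1")
  structure(list(min_sprint = min_sprint, max_sprint = max_sprint,
                 initial_sprint = initial_sprint, grow_factor = grow_factor,
                 shrink_factor = shrink_factor, goal_cc = goal_cc,
                 max_iterations = max_iterations,
                 max_consecutive_rejections = max_consecutive_rejections,
                 archive_depth = archive_depth, temperature = temperature,
                 remove_com = remove_com, seed = as.integer(seed)),
            class = "mdmd_config")
}

#' Run Maxwell's-demon molecular dynamics
#'
#' The demon loop: (1) run a short MD sprint with the chosen propagator,
#' (2) evaluate the scalar progress variable at the sprint end, (3) accept
#' the sprint iff the new value strictly exceeds the best of the last
#' `archive_depth` archived values (ties reject); on acceptance the state is
#' archived and the next sprint grows, on rejection the system is reset to
#' the last archived state, velocities are redrawn from a fresh deterministic
#' substream, and the next sprint shrinks. The demon acts purely by
#' selection: no force derived from the progress variable is ever applied.
#'
#' Termination: progress >= `goal_cc` (status `"goal_reached"`), the
#' iteration budget is exhausted (`"max_iterations"`), or
#' `max_consecutive_rejections` sprints are rejected in a row (`"stalled"`).
#' If the progress function or propagator fails, a partial result with
#' status `"error"` is returned.
#'
#' @param initial an `mdmd_structure`; the model to drive.
#' @param progress function mapping an `mdmd_structure` to a finite scalar
#'   (larger = better), e.g. from [cc_progress()] or [rmsd_progress()].
#' @param propagator engine from [enm_engine()] or [hinge_mc_engine()].
#' @param config an `mdmd_config`.
#' @return object of class `mdmd_result`: list with `accepted_frames`
#'   (an `mdmd_trajectory`, or NULL if nothing was accepted), `cc_trace`
#'   (strictly increasing progress values at accepted states), `initial_cc`,
#'   `sprint_trace`, `log` (per-iteration data.frame: iteration, accepted,
#'   cc, sprint_ps, consecutive_rejections), `status` and `config`.
#' @export
run_mdmd <- function(initial, progress, propagator, config = mdmd_config()) {
  seed_counter <- 0L
  next_seed <- function() {
    seed_counter <<- seed_counter + 1L
    (config$seed + seed_counter * 1000003) %% 2147483629
  }
  cc0 <- progress(initial)
  if (!is.finite(cc0)) stop("progress variable is not finite at the start")

  state <- state_from_structure(initial)
  state <- reset_velocities(state, config$temperature, seed = next_seed(),
                            mass = propagator$mass)
  archive_cc <- cc0
  frames <- list()
  cc_trace <- numeric(0)
  sprint_trace <- numeric(0)
  log <- list()
  status <- "max_iterations"
  sprint <- config$initial_sprint
  consec_rej <- 0L

  if (cc0 >= config$goal_cc) {
    status <- "goal_reached"
  } else {
    for (iter in seq_len(config$max_iterations)) {
      state$rng_state <- next_seed()
      trial <- tryCatch(propagate(propagator, state, sprint),
                        error = function(e) e)
      if (inherits(trial, "error")) {
        status <- "error"
        attr(status, "message") <- conditionMessage(trial)
        break
      }
      val <- tryCatch(progress(set_coords(initial, trial$coordinates)),
                      error = function(e) e)
      if (inherits(val, "error")) {
        status <- "error"
        attr(status, "message") <- conditionMessage(val)
        break
      }
      threshold <- max(tail(archive_cc, config$archive_depth))
      accepted <- is.finite(val) && val > threshold
      if (accepted) {
        if (config$remove_com) trial <- remove_com_motion(trial,
                                                          propagator$mass)
        state <- trial
        archive_cc <- c(archive_cc, val)
        frames[[length(frames) + 1]] <- trial$coordinates
        cc_trace <- c(cc_trace, val)
        sprint_trace <- c(sprint_trace, sprint)
        consec_rej <- 0L
        log[[length(log) + 1]] <- data.frame(
          iteration = iter, accepted = TRUE, cc = val, sprint_ps = sprint,
          consecutive_rejections = 0L)
        sprint <- min(sprint * config$grow_factor, config$max_sprint)
        if (val >= config$goal_cc) {
          status <- "goal_reached"
          break
        }
      } else {
        consec_rej <- consec_rej + 1L
        log[[length(log) + 1]] <- data.frame(
          iteration = iter, accepted = FALSE, cc = val, sprint_ps = sprint,
          consecutive_rejections = consec_rej)
        # reset to last archived state with fresh velocities
        state <- reset_velocities(state, config$temperature,
                                  seed = next_seed(),
                                  mass = propagator$mass)
        sprint <- max(sprint * config$shrink_factor, config$min_sprint)
        if (consec_rej >= config$max_consecutive_rejections) {
          status <- "stalled"
          break
        }
      }
    }
  }

  accepted_frames <- if (length(frames)) {
    new_trajectory(initial, frames, time = seq_along(frames))
  } else NULL
  structure(list(
    accepted_frames = accepted_frames,
    cc_trace = cc_trace,
    initial_cc = cc0,
    sprint_trace = sprint_trace,
    log = if (length(log)) do.call(rbind, log) else
      data.frame(iteration = integer(0), accepted = logical(0),
                 cc = numeric(0), sprint_ps = numeric(0),
                 consecutive_rejections = integer(0)),
    status = status,
    config = config
  ), class = "mdmd_result")
}

#' @export
print.mdmd_result <- function(x, ...) {
  cat(sprintf(
    "mdmd_result: status %s, %d accepted sprints, progress %.4f -> %.4f\n",
    x$status, length(x$cc_trace), x$initial_cc,
    if (length(x$cc_trace)) tail(x$cc_trace, 1) else x$initial_cc))
  invisible(x)
}

#' Final structure of an MdMD run
#' @param initial the structure the run started from.
#' @param result an `mdmd_result`.
#' @return the last accepted conformation (or `initial` if none).
#' @export
final_structure <- function(initial, result) {
  if (is.null(result$accepted_frames)) return(initial)
  frame_structure(result$accepted_frames,
                  n_frames(result$accepted_frames))
}

#' Cross-correlation progress variable
#'
#' Returns a function mapping a structure to the cross-correlation between
#' its simulated density (synthesized directly on the target grid, so the
#' same-geometry precondition of [cross_correlation()] always holds) and the
#' target map. A structure entirely outside the target support scores 0.
#'
#' @param target_map a `density_map` (the experimental/target density).
#' @param kernel a `kernel_params` for the simulated density.
#' @return function: `mdmd_structure` -> numeric in [0, 1].
#' @export
cc_progress <- function(target_map, kernel) {
  if (sum(target_map$values) == 0) stop("target map is all-zero")
  force(kernel)
  function(s) {
    sim <- suppressWarnings(simulate_density(s, grid = target_map,
                                             kernel = kernel))
    if (sum(sim$values) == 0) return(0)
    cross_correlation(sim, target_map)
  }
}

#' Negative-RMSD progress variable
#'
#' Alternative progress variable (MdMD is generic over the scalar it
#' drives): negative RMSD to a reference after superposition, so that
#' "increase" still means "improve". Maximal value 0 at the reference.
#'
#' @param reference an `mdmd_structure`.
#' @param resid,name optional selection filters (see [pair_atoms()]).
#' @return function: `mdmd_structure` -> numeric <= 0.
#' @export
rmsd_progress <- function(reference, resid = NULL, name = NULL) {
  function(s) -superpose(s, reference, resid = resid, name = name)$rmsd
}
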
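#' Velocity rule of the trail model
#'
#' Computes an ant's instantaneous velocity towards the next cell from the
#' next cell's occupancy and pheromone concentration. Four cases:
#'
#' 1. next cell occupied: velocity 0 (hard-core exclusion, no overtaking);
#' 2. next cell empty with meager pheromone (`sigma < 1`, below the
#'    differentiable level): with probability `P` the ant slows to
#'    `max(prev - 0.1, vmin)`, otherwise it keeps its previous velocity
#'    (a blocked ant, `prev = 0`, carries `vmin` instead);
#' 3. next cell empty, differentiable pheromone (`1 <= sigma < sigma_sat`):
#'    deterministic chemotaxis `vmin + a * sigma`;
#' 4. next cell empty, saturated (`sigma >= sigma_sat`): `vmin + a * sigma_sat`.
#'
#' @param prev_velocity The ant's velocity at the previous step
#'   (0 or in `[vmin, vmin + a * sigma_sat]`).
#' @param next_cell_occupied Logical flag, is the cell ahead occupied?
#' @param next_cell_pheromone Pheromone concentration in the cell ahead
#'   (units/cell, >= 0).
#' @param params An [atm_params()] object.
#' @param draw A uniform random number in `[0, 1)`; required only in the
#'   meager-pheromone case (case 2).
#'
#' @return The new velocity in cells/step: 0 or a value in
#'   `[vmin, vmin + a * sigma_sat]`.
#' @examples
#' p <- atm_params()
#' compute_velocity(0.5, FALSE, 40, p)   # chemotaxis: 0.15 + 0.01 * 40
#' compute_velocity(0.5, TRUE, 70, p)    # blocked
#' @export
compute_velocity <- function(prev_velocity, next_cell_occupied,
                             next_cell_pheromone, params, draw = NA_real_) {
  if (!is.finite(next_cell_pheromone) || next_cell_pheromone < 0)
    stop("`next_cell_pheromone` must be a finite value >= 0", call. = FALSE)
  if (isTRUE(next_cell_occupied)) return(0)
  s <- next_cell_pheromone
  if (s < 1) {
    if (is.na(draw))
      stop("a uniform `draw` is required in the meager-pheromone case",
           call. = FALSE)
    prev <- if (prev_velocity > 0) prev_velocity else params$vmin
    if (draw < params$P) max(prev - 0.1, params$vmin) else prev
  } else if (s < params$sigma_sat) {
    params$vmin + params$a * s
  } else {
    params$vmin + params$a * params$sigma_sat
  }
}

#' Advance ant positions on the periodic trail
#'
#' Adds each velocity to each (continuous) position and wraps at the trail
#' end. Because velocities are below one cell/step, each ant crosses at most
#' one cell boundary; the one-ant-per-cell invariant is re-checked on the new
#' positions and a violation aborts (it would indicate a stepper bug).
#'
#' @param positions Per-ant continuous positions in `[0, L)`.
#' @param velocities Per-ant velocities produced by [compute_velocity()]
#'   against the current occupancy.
#' @param L Trail length in cells.
#' @return The new positions, same order.
#' @examples
#' advance_positions(c(3.2, 999.5), c(0.55, 0.95), 1000)
#' @export
advance_positions <- function(positions, velocities, L) {
  p <- positions + velocities
  wrap <- p >= L
  p[wrap] <- p[wrap] - L
  if (anyDuplicated(floor(p)) > 0)
    stop("internal consistency failure: two ants map to one cell",
         call. = FALSE)
  p
}

#' Pheromone evaporation
#'
#' Every cell with positive concentration loses the fraction `re` of its
#' pheromone; empty (zero) cells stay zero. Evaporation acts on all cells,
#' occupied or not.
#'
#' @param pheromone Per-cell concentrations (units/cell, all >= 0).
#' @param re Evaporation rate in `[0, 1]`.
#' @return The evaporated concentrations.
#' @examples
#' evaporate(c(50, 0, 80), re = 0.02)
#' @export
evaporate <- function(pheromone, re) {
  if (!is.numeric(re) || length(re) != 1L || is.na(re) || re < 0 || re > 1)
    stop("`re` must lie in [0, 1]", call. = FALSE)
  if (any(pheromone < 0)) stop("pheromone must be >= 0", call. = FALSE)
  pos <- pheromone > 0
  pheromone[pos] <- pheromone[pos] * (1 - re)
  pheromone
}

#' Pheromone deposition with saturation clamp
#'
#' Applied after [evaporate()] within a step: a depositing cell gains `tau`
#' units, clamped at `sigma_sat`; a cell already at or above `sigma_sat`
#' with an ant in it is clamped to `sigma_sat` regardless of the ant's
#' velocity; all other cells keep the evaporated value. Which occupied
#' cells deposit depends on `params$deposit`: under `"occupied"` (the
#' default) every cell holding an ant deposits each step, which is what
#' the aggregation series assumes for a tightly packed platoon; under
#' `"moving"` only ants with `velocity > 0` deposit, the literal per-case
#' update rule, so blocked ants leave no signal.
#'
#' @param pheromone Per-cell concentrations after evaporation.
#' @param occupied Per-cell logical occupancy at the start of the step.
#' @param velocity Per-cell velocity of the occupant (0 where empty).
#' @param params An [atm_params()] object (`tau`, `sigma_sat`, `deposit`).
#' @return The updated concentrations.
#' @examples
#' p <- atm_params()
#' accumulate(c(49, 79.5), c(TRUE, TRUE), c(0.55, 0.55), p)
#' pm <- atm_params(deposit = "moving")
#' accumulate(49, TRUE, 0, pm)  # blocked ant deposits nothing
#' @export
accumulate <- function(pheromone, occupied, velocity, params) {
  stopifnot(length(occupied) == length(pheromone),
            length(velocity) == length(pheromone))
  sat <- params$sigma_sat
  clamp <- occupied & pheromone >= sat
  dep <- occupied & pheromone < sat
  if (identical(params$deposit, "moving")) dep <- dep & velocity > 0
  pheromone[dep] <- pmin(pheromone[dep] + params$tau, sat)
  pheromone[clamp] <- sat
  pheromone
}

#' Inject a new ant at the entry cell
#'
#' If the entry cell (cell 0) is empty and `draw < inflow`, a new ant with
#' id `N` is appended at the left edge of the entry cell with velocity
#' `vmin`; otherwise nothing changes. Called once per step after the
#' pheromone stage, against the post-update occupancy.
#'
#' @param state A trail state as produced by [atm_state()].
#' @param population An ant population as produced by [atm_population()].
#' @param params An [atm_params()] object.
#' @param draw A uniform random number in `[0, 1)`.
#' @return `list(state = , population = , injected = logical)`.
#' @export
inject_ant <- function(state, population, params, draw) {
  force(draw)  # the draw is consumed whether or not the entry cell is empty
  injected <- state$occupancy[1L] == 0L && draw < params$inflow
  if (injected) {
    n <- length(population$ids)
    population$ids <- c(population$ids, n)
    population$positions <- c(population$positions, 0)
    population$velocities <- c(population$velocities, params$vmin)
    state$occupancy[1L] <- 1L
  }
  list(state = state, population = population, injected = injected)
}

#' Construct a trail state
#'
#' Per-cell occupancy and pheromone plus the time counter. Cells are indexed
#' 0..L-1 internally; vectors are stored 1-based in R, so cell `i` lives at
#' index `i + 1`.
#'
#' @param L Trail length in cells.
#' @param pheromone Per-cell initial concentrations (default all zero).
#' @param occupancy Per-cell 0/1 occupancy (default all empty).
#' @param t Time-step counter.
#' @return A list of class `atm_state`.
#' @export
atm_state <- function(L, pheromone = numeric(L), occupancy = integer(L),
                      t = 0L) {
  stopifnot(length(pheromone) == L, length(occupancy) == L)
  structure(list(pheromone = pheromone, occupancy = as.integer(occupancy),
                 t = as.integer(t)),
            class = "atm_state_obj")
}

#' Construct an ant population
#'
#' @param positions Per-ant continuous positions in `[0, L)`.
#' @param velocities Per-ant velocities (default `vmin` for each).
#' @param params An [atm_params()] object (used for the default velocity).
#' @return A list of class `atm_population` with 0-based ids.
#' @export
atm_population <- function(positions, velocities = NULL, params = NULL) {
  if (is.null(velocities)) {
    stopifnot(!is.null(params))
    velocities <- rep(params$vmin, length(positions))
  }
  structure(list(ids = seq_along(positions) - 1L,
                 positions = as.numeric(positions),
                 velocities = as.numeric(velocities)),
            class = "atm_population")
}

#' One full update step (reference implementation)
#'
#' The naive per-ant stepper used as the independent reference for the
#' optimized C++ run loop. Stage I: all velocities are computed in parallel
#' from the time-t occupancy and pheromone, then all positions advance.
#' Stage II: evaporation, then deposition using the time-t occupancy and the
#' Stage-I velocities. Then injection. One uniform draw is consumed per ant
#' (ascending id) when and only when the meager-pheromone case applies, and
#' one draw per step for injection, so runs are bit-reproducible and
#' bit-identical to [atm_run()] under the same seed.
#'
#' @param state An [atm_state()].
#' @param population An [atm_population()].
#' @param params An [atm_params()].
#' @return `list(state, population, metrics)` where `metrics` is a one-row
#'   data.frame `t, n_ants, density, v_avg, flow` (pre-injection counts).
#' @export
atm_step <- function(state, population, params) {
  L <- params$L
  n0 <- length(population$positions)
  if (n0 == 0L) {
    # empty trail: nothing moves or deposits; pheromone still evaporates
    # and the injection draw is still consumed
    state$pheromone <- evaporate(state$pheromone, params$re)
    state$t <- state$t + 1L
    metrics <- data.frame(t = as.numeric(state$t), n_ants = 0, density = 0,
                          v_avg = NA_real_, flow = NA_real_)
    inj <- inject_ant(state, population, params, draw = runif(1))
    return(list(state = inj$state, population = inj$population,
                metrics = metrics))
  }
  cells <- floor(population$positions)
  newvel <- numeric(n0)
  for (j in seq_len(n0)) {
    nc <- cells[j] + 1
    if (nc == L) nc <- 0
    occ_next <- state$occupancy[nc + 1L] == 1L
    s <- state$pheromone[nc + 1L]
    if (!occ_next && s < 1) {
      newvel[j] <- compute_velocity(population$velocities[j], FALSE, s,
                                    params, draw = runif(1))
    } else {
      newvel[j] <- compute_velocity(population$velocities[j], occ_next, s,
                                    params)
    }
  }
  newpos <- advance_positions(population$positions, newvel, L)

  v_avg <- sum(newvel) / n0
  density <- n0 / L
  metrics <- data.frame(t = as.numeric(state$t + 1L), n_ants = as.numeric(n0),
                        density = density, v_avg = v_avg,
                        flow = density * v_avg)

  ph <- evaporate(state$pheromone, params$re)
  occ_t <- logical(L)
  occ_t[cells + 1L] <- TRUE
  velcell <- numeric(L)
  velcell[cells + 1L] <- newvel
  ph <- accumulate(ph, occ_t, velcell, params)

  occ_new <- integer(L)
  occ_new[floor(newpos) + 1L] <- 1L
  state$pheromone <- ph
  state$occupancy <- occ_new
  state$t <- state$t + 1L
  population$positions <- newpos
  population$velocities <- newvel

  inj <- inject_ant(state, population, params, draw = runif(1))
  list(state = inj$state, population = inj$population, metrics = metrics)
}

#' Full density-sweep run, reference implementation
#'
#' Pure-R counterpart of [atm_run()], kept deliberately naive (per-ant
#' loops) as an oracle: from the same seed the two produce bit-identical
#' trajectories. Starts from a single ant at the entry cell with velocity
#' `vmin` on a pheromone-free trail and iterates [atm_step()] until the
#' trail is full (`N == L`) or `max_steps` is reached.
#'
#' @param params An [atm_params()] object.
#' @param max_steps Step cap (defaults to `params$max_steps`).
#' @param record_trajectory If `TRUE`, keeps per-step positions, velocities
#'   and pheromone snapshots (memory-heavy; small runs only).
#' @return An object of class `atm_run`, see [atm_run()].
#' @export
atm_run_reference <- function(params, max_steps = params$max_steps,
                              record_trajectory = FALSE) {
  if (!is.null(params$seed)) set.seed(params$seed)
  L <- params$L
  state <- atm_state(L)
  state$occupancy[1L] <- 1L
  population <- atm_population(0, params = params)
  rows <- vector("list", 0L)
  traj <- if (record_trajectory)
    list(positions = list(), velocities = list(), pheromone = list())
  termination <- "max_steps"
  step_i <- 0L
  while (step_i < max_steps) {
    res <- atm_step(state, population, params)
    state <- res$state
    population <- res$population
    step_i <- step_i + 1L
    rows[[step_i]] <- res$metrics
    if (record_trajectory) {
      traj$positions[[step_i]] <- population$positions
      traj$velocities[[step_i]] <- population$velocities
      traj$pheromone[[step_i]] <- state$pheromone
    }
    if (length(population$ids) == L) {
      termination <- "density_reached"
      break
    }
  }
  metrics <- do.call(rbind, rows)
  new_atm_run(metrics, params, termination, step_i,
              final = list(positions = population$positions,
                           velocities = population$velocities,
                           pheromone = state$pheromone),
              trajectory = if (record_trajectory) traj)
}

new_atm_run <- function(metrics, params, termination, steps, final,
                        trajectory = NULL) {
  structure(list(metrics = metrics, params = params,
                 termination = termination, steps = steps,
                 truncated = !identical(termination, "density_reached"),
                 final = final, trajectory = trajectory),
            class = "atm_run")
}

#' @export
print.atm_run <- function(x, ...) {
  cat("Ant-trail run:", x$steps, "steps,", length(x$final$positions),
      "ants on", x$params$L, "cells\n")
  cat("  termination:", x$termination,
      if (x$truncated) "(truncated)" else "", "\n")
  cat("  final density:", length(x$final$positions) / x$params$L, "\n")
  invisible(x)
}
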
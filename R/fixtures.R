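#' Deterministic single-cell aggregation trace
#'
#' Tracks one trail cell through which a tightly packed platoon streams:
#' every step the resident (moving) ant deposits `tau`, then the step's
#' evaporation removes the fraction `re`. The recorded `concentration` is
#' the post-evaporation value — what the next arriving ant would sense —
#' so after `m` steps it equals the partial geometric sum
#' `tau * sum_{k=1..m} (1 - re)^k`, term-for-term identical to
#' [finite_aggregation()]. The pheromone stage is deterministic, so this
#' fixture doubles as an exact consistency check between the simulator's
#' Stage-II arithmetic and the closed-form series.
#'
#' @param tau Emission per ant per step (units/step, >= 0).
#' @param re Evaporation rate in `[0, 1]`.
#' @param M Passage length in steps (integer >= 1).
#' @return A data.frame with one row per step: `step`, `post_deposit`
#'   (concentration right after the deposit) and `concentration`
#'   (post-evaporation reading).
#' @examples
#' aggregation_fixture(1, 0.02, 3)  # final concentration 2.881592
#' @export
aggregation_fixture <- function(tau, re, M) {
  if (M < 1 || M != floor(M)) stop("`M` must be an integer >= 1",
                                   call. = FALSE)
  if (re < 0 || re > 1) stop("`re` must lie in [0, 1]", call. = FALSE)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  dep <- numeric(M)
  conc <- numeric(M)
  s <- 0
  for (k in seq_len(M)) {
    dep[k] <- s + tau
    s <- evaporate(dep[k], re)
    conc[k] <- s
  }
  data.frame(step = seq_len(M), post_deposit = dep, concentration = conc)
}

#' Two-ant exclusion scenario on a short ring
#'
#' Places a leader and a follower in adjacent cells of a 10-cell ring whose
#' pheromone is held at saturation (so every velocity is deterministic:
#' free ants move at the top speed `vmin + a * sigma_sat`). Inflow is
#' disabled. The follower is pinned at velocity 0 while the leader still
#' occupies the cell ahead; once the leader crosses its cell boundary the
#' follower is released and a one-cell headway opens — the exclusion
#' mechanism that creates distance headway inside platoons.
#'
#' @param n_steps Number of steps to trace.
#' @return A data.frame with one row per step: `t`, `leader_position`,
#'   `follower_position`, `leader_velocity`, `follower_velocity` and
#'   `headway` (leader position minus follower position).
#' @examples
#' exclusion_fixture()
#' @export
exclusion_fixture <- function(n_steps = 6) {
  params <- atm_params(L = 10L, re = 0.02, inflow = 0, seed = 1L)
  state <- atm_state(params$L,
                     pheromone = rep(params$sigma_sat, params$L))
  # follower id 0 in cell 4, leader id 1 in cell 5
  population <- atm_population(c(4, 5), params = params)
  state$occupancy[c(5L, 6L)] <- 1L
  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    res <- atm_step(state, population, params)
    state <- res$state
    population <- res$population
    rows[[i]] <- data.frame(
      t = i,
      leader_position = population$positions[2L],
      follower_position = population$positions[1L],
      leader_velocity = population$velocities[2L],
      follower_velocity = population$velocities[1L],
      headway = (population$positions[2L] - population$positions[1L]) %%
        params$L)
  }
  do.call(rbind, rows)
}
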
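#' Run a full density sweep of the ant-trail model
#'
#' Starts from a single ant (id 0) at the entry cell with velocity `vmin` on
#' a pheromone-free periodic trail and steps the model until the trail fills
#' (`N == L`, density 1) or `max_steps` is hit. New ants enter at cell 0
#' with probability `inflow` per step whenever it is empty, so the run
#' sweeps slowly through every density and the per-step metrics trace out
#' the fundamental diagram. Fully reproducible from `params$seed`.
#'
#' This is the optimized (compiled) stepper; [atm_run_reference()] is the
#' naive R implementation that produces bit-identical trajectories from the
#' same seed.
#'
#' @param params An [atm_params()] object.
#' @param record_trajectory If `TRUE`, keeps per-step positions, velocities
#'   and pheromone snapshots (memory-heavy; small runs only).
#' @return An object of class `atm_run`: a list with
#'   \describe{
#'     \item{metrics}{data.frame with one row per step: `t`, `n_ants`,
#'       `density` (= N/L), `v_avg` (mean displacement per ant, blocked ants
#'       included), `flow` (= density * v_avg).}
#'     \item{params, termination, steps, truncated}{run protocol echo;
#'       `termination` is `"density_reached"` or `"max_steps"`.}
#'     \item{final}{final `positions`, `velocities`, `pheromone`.}
#'     \item{trajectory}{per-step snapshots, or `NULL`.}
#'   }
#' @examples
#' run <- atm_run(atm_params(L = 50, re = 0.5, inflow = 0.05, seed = 1,
#'                           max_steps = 2000))
#' head(run$metrics)
#' @export
atm_run <- function(params, record_trajectory = FALSE) {
  validate_atm_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- run_atm_cpp(params$L, params$re, params$tau, params$sigma_sat,
                     params$vmin, params$a, params$P, params$inflow,
                     params$max_steps,
                     identical(params$deposit, "moving"),
                     record_trajectory)
  metrics <- data.frame(t = res$t, n_ants = res$n_ants,
                        density = res$density, v_avg = res$v_avg,
                        flow = res$flow)
  trajectory <- NULL
  if (record_trajectory) {
    trajectory <- list(positions = res$traj_positions,
                       velocities = res$traj_velocities,
                       pheromone = res$traj_pheromone)
  }
  new_atm_run(metrics, params, res$termination, res$steps,
              final = list(positions = res$positions,
                           velocities = res$velocities,
                           pheromone = res$pheromone),
              trajectory = trajectory)
}
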
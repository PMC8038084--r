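#' Model parameters for an ant-trail simulation
#'
#' Bundles every fixed constant of the trail model together with the run
#' protocol settings. Defaults are the reference parameter set of the model:
#' a trail of `L = 1000` cells, evaporation rate `re = 0.02` per step,
#' emission `tau = 1` pheromone unit per moving ant per step, antenna
#' saturation at `sigma_sat = 80` units/cell, minimum velocity
#' `vmin = 0.15` cells/step, chemotaxis prefactor `a = 0.01` (so
#' `a * sigma_sat = 0.8` and the top speed is `vmin + a * sigma_sat = 0.95`),
#' slowdown probability `P = 0.7` in the meager-pheromone case, and a slow
#' inflow of `0.001` new ants per step at the entry cell.
#'
#' The velocity range constraint `a * sigma_sat + vmin <= 1` is enforced:
#' one cell per time step is the hard speed limit, which guarantees an ant
#' can cross at most one cell boundary per step.
#'
#' @param L Trail length in cells (integer >= 2).
#' @param re Evaporation rate, fraction of pheromone lost per cell per step,
#'   in `[0, 1]`.
#' @param tau Pheromone emitted by a moving ant per step (units/step, > 0).
#' @param sigma_sat Antenna saturation concentration (units/cell, > 0).
#' @param vmin Minimum velocity (cells/step, in `(0, 1]`).
#' @param a Pheromone-to-velocity prefactor (cells/step per unit, >= 0).
#' @param P Probability of slowing down when the pheromone ahead is below
#'   the differentiable level, in `[0, 1]`.
#' @param inflow Per-step probability of injecting a new ant at the entry
#'   cell when it is empty, in `[0, 1]`.
#' @param seed Integer RNG seed, or `NULL` to leave the RNG state alone.
#' @param max_steps Hard cap on the number of steps of a run.
#' @param deposit Deposition rule: `"occupied"` (default) deposits `tau`
#'   into every occupied cell each step, the behaviour the aggregation
#'   theory assumes (a tightly packed platoon adds one deposit per step
#'   even though most of its members are blocked) and the one that
#'   produces the rise-up and the high critical density; `"moving"`
#'   restricts deposition to ants with positive velocity, the literal
#'   per-case reading of the update rule, under which standing platoons
#'   leave no signal and the free-flow phase ends much earlier. See the
#'   methods vignette for the full discussion.
#'
#' @return An object of class `atm_params` (a validated named list).
#' @examples
#' p <- atm_params(L = 200, inflow = 0.005, seed = 1)
#' p$re
#' @export
atm_params <- function(L = 1000L, re = 0.02, tau = 1, sigma_sat = 80,
                       vmin = 0.15, a = 0.01, P = 0.7, inflow = 0.001,
                       seed = NULL, max_steps = 5e6,
                       deposit = c("occupied", "moving")) {
  p <- structure(list(
    L = as.integer(L), re = as.numeric(re), tau = as.numeric(tau),
    sigma_sat = as.numeric(sigma_sat), vmin = as.numeric(vmin),
    a = as.numeric(a), P = as.numeric(P), inflow = as.numeric(inflow),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    max_steps = as.numeric(max_steps),
    deposit = match.arg(deposit)
  ), class = "atm_params")
  validate_atm_params(p)
  p
}

validate_atm_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!is.integer(p$L) || length(p$L) != 1L || is.na(p$L) || p$L < 2L)
    stop("`L` must be a single integer >= 2", call. = FALSE)
  if (!num1(p$re) || p$re < 0 || p$re > 1)
    stop("`re` must lie in [0, 1]", call. = FALSE)
  if (!num1(p$tau) || p$tau <= 0)
    stop("`tau` must be > 0", call. = FALSE)
  if (!num1(p$sigma_sat) || p$sigma_sat <= 0)
    stop("`sigma_sat` must be > 0", call. = FALSE)
  if (!num1(p$vmin) || p$vmin <= 0 || p$vmin > 1)
    stop("`vmin` must lie in (0, 1]", call. = FALSE)
  if (!num1(p$a) || p$a < 0)
    stop("`a` must be >= 0", call. = FALSE)
  if (!num1(p$P) || p$P < 0 || p$P > 1)
    stop("`P` must lie in [0, 1]", call. = FALSE)
  if (!num1(p$inflow) || p$inflow < 0 || p$inflow > 1)
    stop("`inflow` must lie in [0, 1]", call. = FALSE)
  if (!num1(p$max_steps) || p$max_steps < 1)
    stop("`max_steps` must be >= 1", call. = FALSE)
  if (!is.character(p$deposit) || length(p$deposit) != 1L ||
      !p$deposit %in% c("occupied", "moving"))
    stop("`deposit` must be \"occupied\" or \"moving\"", call. = FALSE)
  # vmax = 1: top speed vmin + a*sigma_sat must not exceed one cell/step
  if (p$a * p$sigma_sat + p$vmin > 1 + 1e-12)
    stop("`a * sigma_sat + vmin` must not exceed 1 (one cell per step)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.atm_params <- function(x, ...) {
  cat("Ant-trail model parameters\n")
  cat(sprintf("  trail:      L = %d cells (periodic)\n", x$L))
  cat(sprintf("  pheromone:  re = %g, tau = %g, sigma_sat = %g\n",
              x$re, x$tau, x$sigma_sat))
  cat(sprintf("  velocity:   vmin = %g, a = %g (top speed %g), P = %g\n",
              x$vmin, x$a, x$vmin + x$a * x$sigma_sat, x$P))
  cat(sprintf("  protocol:   inflow = %g, max_steps = %g, seed = %s\n",
              x$inflow, x$max_steps,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  cat(sprintf("  deposition: every %s cell gains tau per step\n",
              if (x$deposit == "occupied") "occupied" else "occupied-and-moving"))
  invisible(x)
}
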
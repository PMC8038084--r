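#' Pheromone aggregated by a finite platoon passage
#'
#' Closed-form concentration left in a cell after a tightly packed platoon
#' has streamed through it for `M` steps: each step the resident ant
#' deposits `tau` units and the step's evaporation removes the fraction
#' `re`, so the deposit made `k` steps before the reading has decayed to
#' `tau * (1 - re)^k`. The total is the geometric partial sum
#' `tau * sum_{k=1..M} (1 - re)^k`, returned unclamped (no saturation).
#'
#' @param tau Emission per ant per step (units/step).
#' @param re Evaporation rate in `[0, 1]`.
#' @param M Passage length in steps (integer >= 0).
#' @return The aggregated concentration (units/cell).
#' @examples
#' finite_aggregation(1, 0.02, 3)  # 0.98 + 0.9604 + 0.941192
#' @export
finite_aggregation <- function(tau, re, M) {
  if (re < 0 || re > 1) stop("`re` must lie in [0, 1]", call. = FALSE)
  if (M < 0 || M != floor(M)) stop("`M` must be an integer >= 0",
                                   call. = FALSE)
  if (M == 0) return(0)
  tau * sum((1 - re)^(seq_len(M)))
}

#' Converged aggregation behind an infinite platoon
#'
#' Limit of [finite_aggregation()] as the platoon length grows: the
#' geometric series converges (for `re > 0`) to `tau * (1 - re) / re`,
#' clamped at the antenna saturation level. This is the highest
#' concentration a trail cell ever reaches, so it controls whether the
#' communication channel saturates.
#'
#' @param tau Emission per ant per step (units/step).
#' @param re Evaporation rate in `(0, 1]`.
#' @param sigma_sat Saturation concentration (units/cell).
#' @param clamp If `FALSE`, return the raw series limit without the
#'   saturation clamp.
#' @return The converged concentration (units/cell).
#' @examples
#' converged_aggregation(1, 0.02, 80)  # 49
#' converged_aggregation(1, 0.01, 80)  # clamped at 80 (raw value 99)
#' @export
converged_aggregation <- function(tau, re, sigma_sat, clamp = TRUE) {
  if (re <= 0 || re > 1)
    stop("the aggregation series diverges: `re` must lie in (0, 1]",
         call. = FALSE)
  raw <- tau * (1 - re) / re
  if (clamp) min(raw, sigma_sat) else raw
}

#' Time for aggregated pheromone to deplete below the differentiable level
#'
#' Starting from concentration `sigma0`, pure evaporation gives
#' `sigma0 * (1 - re)^D`; the depletion time is the `D` at which this
#' reaches the differentiable threshold 1, i.e.
#' `max(0, -log(sigma0) / log(1 - re))`. It is the minimum headway (in
#' steps) after which a following platoon's leader finds no readable
#' signal in the cell.
#'
#' @param sigma0 Starting concentration (units/cell, > 0).
#' @param re Evaporation rate in `(0, 1)`.
#' @return Depletion time `D` in steps (real-valued, >= 0).
#' @examples
#' depletion_time(49, 0.02)   # about 192.6
#' depletion_time(80, 0.19)   # about 20.8
#' @export
depletion_time <- function(sigma0, re) {
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("`sigma0` must be > 0", call. = FALSE)
  if (!is.finite(re) || re <= 0 || re >= 1)
    stop("`re` must lie strictly inside (0, 1)", call. = FALSE)
  max(0, -log(sigma0) / log(1 - re))
}

#' Minimum traversal time over a distance at constant velocity
#'
#' `distance / velocity`: the approximate time a follower needs to reach a
#' cell `distance` cells ahead while travelling at `velocity`. At the
#' model's minimum velocity 0.15 a one-cell headway takes 6.67 steps
#' (printed as 6.66 in two-decimal truncation).
#'
#' @param distance Distance in cells (> 0).
#' @param velocity Velocity in cells/step (> 0).
#' @return Time in steps.
#' @examples
#' min_traversal_time(1, 0.15)
#' @export
min_traversal_time <- function(distance, velocity) {
  if (!is.finite(distance) || distance <= 0)
    stop("`distance` must be > 0", call. = FALSE)
  if (!is.finite(velocity) || velocity <= 0)
    stop("`velocity` must be > 0", call. = FALSE)
  distance / velocity
}

#' Evaporation rate at the minimal/active state boundary
#'
#' The evaporation rate above which even the densest trail signal dies
#' before it can be read: the root in (0, 1) of
#' `tau * (1 - re) / re * (1 - re)^(1 / vmin) = 1`, i.e. the converged
#' aggregation decays below the differentiable level 1 within the one-cell
#' traversal time `D = 1 / vmin` of a follower moving at `vmin`. Found by
#' bisection (the residual is strictly decreasing in `re`).
#'
#' @param tau Emission per ant per step (units/step, > 0).
#' @param vmin Minimum velocity (cells/step, in `(0, 1]`).
#' @param tol Absolute bisection tolerance.
#' @return The boundary evaporation rate (0.1932... at the defaults,
#'   quoted as 0.19).
#' @examples
#' round(minimal_state_boundary(1, 0.15), 2)
#' @export
minimal_state_boundary <- function(tau = 1, vmin = 0.15, tol = 1e-8) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (vmin <= 0 || vmin > 1) stop("`vmin` must lie in (0, 1]", call. = FALSE)
  f <- function(r) tau * (1 - r) / r * (1 - r)^(1 / vmin) - 1
  lo <- 1e-6
  hi <- 1 - 1e-6
  if (f(lo) <= 0 || f(hi) >= 0)
    stop("no sign change on (0, 1): no minimal-state boundary",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Evaporation rate at the active/inactive state boundary
#'
#' Below this rate the converged aggregation `tau * (1 - re) / re` exceeds
#' the saturation level, so the channel saturates and carries no local
#' information. Solving for equality gives the closed form
#' `re = tau / (sigma_sat + tau)`.
#'
#' @param tau Emission per ant per step (units/step, > 0).
#' @param sigma_sat Saturation concentration (units/cell, > 0).
#' @return The boundary evaporation rate (1/81 = 0.012345... at the
#'   defaults, quoted as 0.012).
#' @examples
#' round(inactive_state_boundary(1, 80), 3)
#' @export
inactive_state_boundary <- function(tau = 1, sigma_sat = 80) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (sigma_sat <= 0) stop("`sigma_sat` must be > 0", call. = FALSE)
  tau / (sigma_sat + tau)
}

#' Emission rate at which the trail first saturates
#'
#' Inverts the converged aggregation for `tau`: at emission
#' `sigma_sat * re / (1 - re)` the infinite-platoon concentration first
#' reaches the saturation level, beyond which extra deposit is undetectable.
#'
#' @param re Evaporation rate in `(0, 1)`.
#' @param sigma_sat Saturation concentration (units/cell, > 0).
#' @return The saturating emission rate (1.6326... at `re = 0.02`,
#'   `sigma_sat = 80`, quoted as 1.63).
#' @examples
#' round(saturation_tau(0.02, 80), 2)
#' @export
saturation_tau <- function(re, sigma_sat) {
  if (re <= 0 || re >= 1) stop("`re` must lie in (0, 1)", call. = FALSE)
  if (sigma_sat <= 0) stop("`sigma_sat` must be > 0", call. = FALSE)
  sigma_sat * re / (1 - re)
}

#' Classify the communication state of a trail
#'
#' Labels an evaporation rate as `minimal` (signal dies before it can be
#' read), `active` (signal encodes recent-past flow) or `inactive` (signal
#' saturates into uninformativeness), using the two analytic boundaries
#' computed from [minimal_state_boundary()] and
#' [inactive_state_boundary()]. The boundaries are compared at the
#' precision at which the analysis quotes them (`digits`; 2 for the minimal
#' boundary, 3 for the inactive one — set to `Inf` for the raw roots), and
#' the boundaries themselves belong to the active state (closed interval).
#'
#' @param re Evaporation rate to classify, in `[0, 1]`.
#' @param tau Emission per ant per step (units/step).
#' @param sigma_sat Saturation concentration (units/cell).
#' @param vmin Minimum velocity (cells/step).
#' @param digits Length-2 integer: rounding precision for the minimal and
#'   inactive boundaries used in the comparison.
#' @return An object of class `atm_state`: list with `label`,
#'   `boundary_minimal`, `boundary_inactive` (raw roots),
#'   `boundary_minimal_used`, `boundary_inactive_used` (rounded values the
#'   label was decided against) and the echoed inputs.
#' @examples
#' classify_state(0.02)$label   # "active"
#' classify_state(0.5)$label    # "minimal"
#' classify_state(0.001)$label  # "inactive"
#' @export
classify_state <- function(re, tau = 1, sigma_sat = 80, vmin = 0.15,
                           digits = c(2L, 3L)) {
  if (re < 0 || re > 1) stop("`re` must lie in [0, 1]", call. = FALSE)
  b_min <- minimal_state_boundary(tau, vmin)
  b_inact <- inactive_state_boundary(tau, sigma_sat)
  b_min_used <- if (is.finite(digits[1L])) round(b_min, digits[1L]) else b_min
  b_inact_used <- if (is.finite(digits[2L])) round(b_inact, digits[2L])
                  else b_inact
  if (b_inact_used >= b_min_used)
    stop("degenerate parameters: no active window between the boundaries",
         call. = FALSE)
  label <- if (re > b_min_used) "minimal"
           else if (re < b_inact_used) "inactive"
           else "active"
  structure(list(label = label,
                 boundary_minimal = b_min,
                 boundary_inactive = b_inact,
                 boundary_minimal_used = b_min_used,
                 boundary_inactive_used = b_inact_used,
                 re = re, tau = tau, sigma_sat = sigma_sat, vmin = vmin),
            class = "atm_state")
}

#' @export
print.atm_state <- function(x, ...) {
  cat(sprintf("Trail communication state: %s\n", x$label))
  cat(sprintf("  re = %g; boundaries: inactive < %g <= active <= %g < minimal\n",
              x$re, x$boundary_inactive_used, x$boundary_minimal_used))
  invisible(x)
}

#' Closed-form pheromone report for one parameter set
#'
#' Convenience bundle of every analytic quantity for a parameter set: raw
#' and clamped converged aggregation, depletion time of the converged
#' concentration, both state boundaries, the saturating emission rate and
#' the state label. This is what the command-line `analytics` subcommand
#' prints as JSON.
#'
#' @inheritParams classify_state
#' @return A named list.
#' @export
analytics_report <- function(re, tau = 1, sigma_sat = 80, vmin = 0.15) {
  st <- classify_state(re, tau, sigma_sat, vmin)
  raw <- converged_aggregation(tau, re, sigma_sat, clamp = FALSE)
  clamped <- converged_aggregation(tau, re, sigma_sat)
  list(
    inputs = list(re = re, tau = tau, sigma_sat = sigma_sat, vmin = vmin),
    converged_aggregation_raw = raw,
    converged_aggregation = clamped,
    depletion_time = if (re > 0 && re < 1 && clamped > 0)
      depletion_time(clamped, re) else NA_real_,
    one_cell_traversal_time = min_traversal_time(1, vmin),
    boundary_minimal = st$boundary_minimal,
    boundary_inactive = st$boundary_inactive,
    saturation_tau = if (re > 0 && re < 1) saturation_tau(re, sigma_sat)
                     else NA_real_,
    state = st$label
  )
}
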
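#' Per-step traffic observables
#'
#' Density, average velocity and flow for one time step. The average
#' velocity is the mean displacement over *all* ants, blocked ants
#' (velocity 0) included; flow is `density * v_avg` by definition.
#'
#' @param velocities Per-ant velocities for the step (cells/step).
#' @param L Trail length in cells.
#' @param t Time-step label (optional).
#' @return One-row data.frame: `t, n_ants, density, v_avg, flow`.
#' @examples
#' step_metrics(rep(0.15, 100), L = 1000)
#' @export
step_metrics <- function(velocities, L, t = NA_real_) {
  n <- length(velocities)
  if (n == 0L) stop("metrics are undefined for an empty population",
                    call. = FALSE)
  v_avg <- sum(velocities) / n
  density <- n / L
  data.frame(t = as.numeric(t), n_ants = as.numeric(n), density = density,
             v_avg = v_avg, flow = density * v_avg)
}

#' Bin per-step metrics into a fundamental diagram
#'
#' Groups the steps of a run by density bin and averages velocity and flow
#' per bin, producing the empirical velocity-density and flow-density
#' relations. Because the slow-inflow protocol lets traffic establish at
#' each density, no burn-in is needed by default; `burn_in` drops rows with
#' `t < burn_in` if requested.
#'
#' @param metrics A per-step metrics data.frame (from [atm_run()]).
#' @param bin_width Density bin width, in `(0, 0.5]`.
#' @param burn_in Steps to drop from the start.
#' @return A data.frame of class `atm_fd`, one row per occupied bin, sorted
#'   by `bin_center`: `bin_center, mean_v, mean_flow, count`. The bin width
#'   is carried in `attr(, "bin_width")`.
#' @export
bin_fundamental_diagram <- function(metrics, bin_width = 0.005,
                                    burn_in = 0) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      is.na(bin_width) || bin_width <= 0 || bin_width > 0.5)
    stop("`bin_width` must lie in (0, 0.5]", call. = FALSE)
  m <- metrics[metrics$t >= burn_in, , drop = FALSE]
  if (nrow(m) == 0L) stop("no metrics rows left after burn-in", call. = FALSE)
  idx <- ceiling(m$density / bin_width)
  idx[idx < 1L] <- 1L
  f <- factor(idx)
  counts <- tabulate(f)
  mean_v <- as.numeric(tapply(m$v_avg, f, mean))
  mean_flow <- as.numeric(tapply(m$flow, f, mean))
  centers <- (as.numeric(levels(f)) - 0.5) * bin_width
  ord <- order(centers)
  fd <- data.frame(bin_center = centers[ord], mean_v = mean_v[ord],
                   mean_flow = mean_flow[ord], count = counts[ord])
  attr(fd, "bin_width") <- bin_width
  class(fd) <- c("atm_fd", "data.frame")
  fd
}

#' Critical density of a fundamental diagram
#'
#' The density at the free-flow/jamming junction, operationalized as the bin
#' center maximizing the moving-average-smoothed binned flow. Ties break
#' toward the lower density. The window is centered; at the edges it
#' shrinks to the available bins.
#'
#' @param fd A fundamental diagram from [bin_fundamental_diagram()].
#' @param smooth_window Moving-average window in bins (odd recommended).
#' @return The critical density (a bin center).
#' @export
critical_density <- function(fd, smooth_window = 5L) {
  n <- nrow(fd)
  if (n < smooth_window)
    stop("insufficient data: fewer occupied bins than `smooth_window`",
         call. = FALSE)
  sm <- smooth_moving_average(fd$mean_flow, smooth_window)
  fd$bin_center[which.max(sm)]
}

# centered moving average with shrinking edge windows
smooth_moving_average <- function(x, window) {
  n <- length(x)
  h_lo <- (window - 1L) %/% 2L
  h_hi <- window - 1L - h_lo
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h_lo)
    hi <- min(n, i + h_hi)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Detect platoons on the ring
#'
#' Partitions the ants into maximal runs ("platoons") in which consecutive
#' ants are separated by at most `gap_threshold` empty cells, computed on
#' the periodic trail. A single ant forms one platoon; if every gap is
#' within the threshold the whole population is one platoon.
#'
#' @param positions Per-ant continuous positions (or occupied cell indices).
#' @param L Trail length in cells.
#' @param gap_threshold Maximum number of empty cells between members of
#'   the same platoon.
#' @return A data.frame of class `atm_platoons`, one row per platoon:
#'   `platoon, size, span, gap_to_next` (`span` in cells from first to last
#'   member; `gap_to_next` empty cells to the next platoon downstream, `NA`
#'   for a single all-encompassing platoon). Member cells are in
#'   `attr(, "members")`; the threshold in `attr(, "gap_threshold")`.
#' @examples
#' detect_platoons(c(3, 4, 5, 40, 41), L = 100, gap_threshold = 2)
#' @export
detect_platoons <- function(positions, L, gap_threshold = 2) {
  if (length(positions) == 0L) stop("no ants", call. = FALSE)
  cells <- sort(floor(positions))
  n <- length(cells)
  if (anyDuplicated(cells) > 0)
    stop("two ants share a cell", call. = FALSE)
  if (n == 1L) {
    out <- data.frame(platoon = 1L, size = 1L, span = 1L,
                      gap_to_next = NA_real_)
    attr(out, "members") <- list(cells)
    attr(out, "gap_threshold") <- gap_threshold
    class(out) <- c("atm_platoons", "data.frame")
    return(out)
  }
  # gap[i]: empty cells between ant i and the next ant (cyclic)
  gaps <- c(diff(cells) - 1, cells[1L] + L - cells[n] - 1)
  breaks <- which(gaps > gap_threshold)
  if (length(breaks) == 0L) {
    out <- data.frame(platoon = 1L, size = n, span = L,
                      gap_to_next = NA_real_)
    attr(out, "members") <- list(cells)
    attr(out, "gap_threshold") <- gap_threshold
    class(out) <- c("atm_platoons", "data.frame")
    return(out)
  }
  # platoon k runs from the ant after break k-1 to the ant at break k
  nb <- length(breaks)
  members <- vector("list", nb)
  gap_to_next <- numeric(nb)
  for (k in seq_len(nb)) {
    from <- if (k == 1L) breaks[nb] + 1L else breaks[k - 1L] + 1L
    if (from > n) from <- from - n
    to <- breaks[k]
    ix <- if (from <= to) from:to else c(from:n, 1:to)
    members[[k]] <- cells[ix]
    gap_to_next[k] <- gaps[breaks[k]]
  }
  size <- vapply(members, length, integer(1))
  span <- vapply(members, function(m) {
    # span on the ring: a wrapped platoon crosses the origin exactly once
    if (all(diff(m) >= 0)) m[length(m)] - m[1L] + 1
    else (L - m[1L]) + m[length(m)] + 1
  }, numeric(1))
  out <- data.frame(platoon = seq_len(nb), size = size, span = span,
                    gap_to_next = gap_to_next)
  attr(out, "members") <- members
  attr(out, "gap_threshold") <- gap_threshold
  class(out) <- c("atm_platoons", "data.frame")
  out
}

#' Sweep the evaporation rate and record critical densities
#'
#' Runs the full slow-inflow protocol for each evaporation rate in
#' `re_grid` (crossed with `seeds`), bins the resulting metrics and records
#' the critical density of each run.
#'
#' @param params_base An [atm_params()] object providing everything but
#'   `re` and `seed`.
#' @param re_grid Evaporation rates to simulate, each in `[0, 1]`.
#' @param seeds Integer seeds; each `re` is run once per seed.
#' @param bin_width,smooth_window,burn_in Passed to
#'   [bin_fundamental_diagram()] and [critical_density()].
#' @return A data.frame sorted by `re`: one row per `(re, seed)` with
#'   `re, seed, critical_density, truncated, steps`.
#' @export
sweep_evaporation <- function(params_base, re_grid, seeds = 1L,
                              bin_width = 0.005, smooth_window = 5L,
                              burn_in = 0) {
  if (any(re_grid < 0 | re_grid > 1))
    stop("all `re_grid` values must lie in [0, 1]", call. = FALSE)
  grid <- expand.grid(seed = as.integer(seeds), re = as.numeric(re_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params_base
    p$re <- grid$re[i]
    p$seed <- grid$seed[i]
    run <- atm_run(p)
    fd <- bin_fundamental_diagram(run$metrics, bin_width = bin_width,
                                  burn_in = burn_in)
    data.frame(re = p$re, seed = p$seed,
               critical_density = critical_density(fd, smooth_window),
               truncated = run$truncated, steps = run$steps)
  })
  out <- do.call(rbind, rows)
  out[order(out$re, out$seed), , drop = FALSE]
}

#' Sweep the pheromone emission rate and record critical densities
#'
#' Same protocol as [sweep_evaporation()] but varying `tau` at fixed `re`,
#' probing how the weight of a single ant's deposit shifts the free-flow
#' range of the fundamental diagram.
#'
#' @inheritParams sweep_evaporation
#' @param tau_grid Emission rates to simulate, each > 0.
#' @return A data.frame sorted by `tau`: one row per `(tau, seed)` with
#'   `tau, seed, critical_density, truncated, steps`.
#' @export
sweep_emission <- function(params_base, tau_grid, seeds = 1L,
                           bin_width = 0.005, smooth_window = 5L,
                           burn_in = 0) {
  if (any(tau_grid <= 0))
    stop("all `tau_grid` values must be > 0", call. = FALSE)
  grid <- expand.grid(seed = as.integer(seeds), tau = as.numeric(tau_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params_base
    p$tau <- grid$tau[i]
    p$seed <- grid$seed[i]
    run <- atm_run(p)
    fd <- bin_fundamental_diagram(run$metrics, bin_width = bin_width,
                                  burn_in = burn_in)
    data.frame(tau = p$tau, seed = p$seed,
               critical_density = critical_density(fd, smooth_window),
               truncated = run$truncated, steps = run$steps)
  })
  out <- do.call(rbind, rows)
  out[order(out$tau, out$seed), , drop = FALSE]
}
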
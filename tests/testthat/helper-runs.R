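# Small-parameter helpers shared across test files.

small_params <- function(...) {
  defaults <- list(L = 50L, inflow = 0.02, seed = 101L, max_steps = 60000)
  args <- utils::modifyList(defaults, list(...))
  do.call(atm_params, args)
}

# ant indices (1-based) in ascending-position order
ring_order <- function(pos) order(pos)

# rotate a cyclic sequence so it starts at `start`
rotate_to <- function(x, start) {
  s <- match(start, x)
  if (is.na(s)) return(NULL)
  c(x[s:length(x)], x[seq_len(s - 1L)])
}

# Invariant scan over a recorded trajectory: hard-core exclusion, velocity
# support {0} u [vmin, vmin + a*sigma_sat], pheromone in [0, sigma_sat],
# and no overtaking (the cyclic order of ants already present never
# changes; injected ants only splice in at the entry cell).
check_run_invariants <- function(run) {
  p <- run$params
  top <- p$vmin + p$a * p$sigma_sat
  ok <- list(cells = TRUE, velocities = TRUE, pheromone = TRUE,
             order = TRUE)
  prev_ids <- NULL
  for (i in seq_along(run$trajectory$positions)) {
    pos <- run$trajectory$positions[[i]]
    vel <- run$trajectory$velocities[[i]]
    ph <- run$trajectory$pheromone[[i]]
    if (anyDuplicated(floor(pos)) > 0) ok$cells <- FALSE
    if (!all(vel == 0 | (vel >= p$vmin - 1e-12 & vel <= top + 1e-12)))
      ok$velocities <- FALSE
    if (any(ph < 0) || any(ph > p$sigma_sat + 1e-12)) ok$pheromone <- FALSE
    ids <- ring_order(pos)
    if (!is.null(prev_ids) && length(prev_ids) >= 2L) {
      surviving <- ids[ids %in% prev_ids]
      if (!identical(rotate_to(surviving, prev_ids[1L]), prev_ids))
        ok$order <- FALSE
    }
    prev_ids <- ids
  }
  ok
}
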
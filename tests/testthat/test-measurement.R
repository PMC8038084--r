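test_that("per-step metrics average over all ants including blocked ones", {
  m <- step_metrics(rep(0.15, 100), L = 1000)
  expect_equal(m$density, 0.1)
  expect_equal(m$v_avg, 0.15)
  expect_equal(m$flow, 0.015)
  m2 <- step_metrics(c(0.95, 0), L = 1000)
  expect_equal(m2$v_avg, 0.475)
  m3 <- step_metrics(rep(0, 50), L = 50)
  expect_equal(m3$density, 1)
  expect_equal(m3$v_avg, 0)
  expect_equal(m3$flow, 0)
  expect_error(step_metrics(numeric(0), 50), "empty")
})

test_that("binning a constant-density table reproduces the column means", {
  m <- data.frame(t = 1:100, n_ants = 30, density = 0.3,
                  v_avg = runif(100, 0.1, 0.2))
  m$flow <- m$density * m$v_avg
  fd <- bin_fundamental_diagram(m, bin_width = 0.01)
  expect_identical(nrow(fd), 1L)
  expect_equal(fd$mean_v, mean(m$v_avg))
  expect_equal(fd$mean_flow, mean(m$flow))
  expect_identical(fd$count, 100L)
})

test_that("bins are disjoint, ordered and no more numerous than 1/bin_width", {
  run <- atm_run(small_params(inflow = 0.1, max_steps = 200000))
  fd <- bin_fundamental_diagram(run$metrics, bin_width = 0.01)
  expect_lte(nrow(fd), 100L)
  expect_true(all(diff(fd$bin_center) > 0))
  expect_identical(sum(fd$count), nrow(run$metrics))
  expect_error(bin_fundamental_diagram(run$metrics, bin_width = 0.7),
               "bin_width")
})

test_that("burn-in drops early steps", {
  m <- data.frame(t = 1:100, n_ants = 30, density = 0.3, v_avg = 0.15,
                  flow = 0.045)
  fd <- bin_fundamental_diagram(m, bin_width = 0.01, burn_in = 51)
  expect_identical(fd$count, 50L)
})

test_that("critical density finds the apex of a triangular flow profile", {
  centers <- seq(0.005, 0.995, by = 0.01)
  flow <- 1 - abs(centers - 0.605)  # apex exactly at a bin center
  fd <- structure(data.frame(bin_center = centers, mean_v = flow / centers,
                             mean_flow = flow, count = 10L),
                  class = c("atm_fd", "data.frame"))
  expect_equal(critical_density(fd, smooth_window = 5), 0.605)
})

test_that("critical density matches a brute-force smoothed argmax under noise", {
  centers <- seq(0.0025, 0.9975, by = 0.005)
  base <- ifelse(centers <= 0.45, centers, 0.9 - centers) # apex at 0.45
  set.seed(99)
  for (rep in 1:5) {
    noisy <- base + rnorm(length(base), sd = 0.004)
    fd <- structure(data.frame(bin_center = centers, mean_v = 0.15,
                               mean_flow = noisy, count = 5L),
                    class = c("atm_fd", "data.frame"))
    # independent oracle: explicit loop over all centered windows
    w <- 5L
    n <- length(noisy)
    sm <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
      sm[i] <- mean(noisy[lo:hi])
    }
    expect_equal(critical_density(fd, w), centers[which.max(sm)])
    # and the estimate stays within one bin of the true apex
    expect_lt(abs(critical_density(fd, w) - 0.45), 0.05)
  }
})

test_that("ties in smoothed flow break toward the lower density", {
  centers <- seq(0.05, 0.95, by = 0.1)
  flow <- c(1, 2, 3, 3, 3, 3, 3, 3, 2, 1)  # flat smoothed top, tied max
  fd <- structure(data.frame(bin_center = centers, mean_v = 1,
                             mean_flow = flow, count = 1L),
                  class = c("atm_fd", "data.frame"))
  sm_manual <- sapply(seq_along(flow), function(i) {
    lo <- max(1, i - 2); hi <- min(length(flow), i + 2)
    mean(flow[lo:hi])
  })
  first_max <- which.max(sm_manual)
  expect_equal(critical_density(fd, 5L), centers[first_max])
  expect_error(critical_density(fd[1:3, ], 5L), "insufficient")
})

test_that("platoon detection partitions the ring by gap threshold", {
  p <- detect_platoons(c(3, 4, 5, 40, 41), L = 100, gap_threshold = 2)
  expect_identical(nrow(p), 2L)
  expect_setequal(p$size, c(3L, 2L))
  # all adjacent: one platoon
  p1 <- detect_platoons(10:15, L = 100, gap_threshold = 2)
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$size, 6L)
  # periodic adjacency across the origin
  p2 <- detect_platoons(c(99, 0), L = 100, gap_threshold = 1)
  expect_identical(nrow(p2), 1L)
  expect_identical(p2$size, 2L)
  expect_equal(p2$span, 2)
  # a single ant is its own platoon
  p3 <- detect_platoons(42.7, L = 100)
  expect_identical(nrow(p3), 1L)
  # gaps above the threshold split; member sets partition the ants
  p4 <- detect_platoons(c(0, 1, 2, 10, 11, 98), L = 100, gap_threshold = 2)
  expect_identical(nrow(p4), 2L)   # 98,0,1,2 wrap-joined; 10,11 separate
  expect_setequal(unlist(attr(p4, "members")), c(0, 1, 2, 10, 11, 98))
  expect_setequal(p4$size, c(4L, 2L))
})

test_that("the evaporation sweep returns one ordered row per re and seed", {
  base <- small_params(L = 30L, inflow = 0.1, max_steps = 50000)
  sw <- sweep_evaporation(base, re_grid = c(0.5, 0.02), seeds = c(1L, 2L),
                          bin_width = 0.02, smooth_window = 3L)
  expect_identical(nrow(sw), 4L)
  expect_true(!is.unsorted(sw$re))
  expect_true(all(sw$critical_density > 0 & sw$critical_density <= 1))
  expect_false(any(sw$truncated))
  # same seed, same re: reproducible
  sw2 <- sweep_evaporation(base, re_grid = 0.02, seeds = 1L,
                           bin_width = 0.02, smooth_window = 3L)
  expect_equal(sw2$critical_density,
               sw$critical_density[sw$re == 0.02 & sw$seed == 1L])
  expect_error(sweep_evaporation(base, re_grid = 1.2), "re_grid")
})

test_that("replicate seeds agree on the critical density within a bin width", {
  # at small L the flow curve is noisy; a window wide enough to average the
  # noise brings replicates to within one bin of each other
  base <- atm_params(L = 100L, re = 0.5, inflow = 0.05, max_steps = 3e6)
  sw <- sweep_evaporation(base, re_grid = 0.5, seeds = c(1L, 2L, 3L),
                          bin_width = 0.02, smooth_window = 9L)
  expect_lte(max(sw$critical_density) - min(sw$critical_density),
             0.02 + 1e-9)
})
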
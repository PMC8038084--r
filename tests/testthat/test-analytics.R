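test_that("the finite aggregation series is an exact geometric partial sum", {
  expect_equal(finite_aggregation(1, 0.02, 3), 0.98 + 0.9604 + 0.941192)
  expect_equal(finite_aggregation(2, 0.3, 1), 2 * 0.7)
  expect_identical(finite_aggregation(1, 0.5, 0), 0)
  expect_identical(finite_aggregation(1, 1, 10), 0)
  expect_error(finite_aggregation(1, 1.2, 5), "re")
  expect_error(finite_aggregation(1, 0.2, 2.5), "M")
})

test_that("finite aggregation is non-decreasing in M and converges", {
  for (re in c(0.01, 0.02, 0.1, 0.5)) {
    vals <- vapply(c(1, 5, 20, 100, 1000, 5000),
                   function(m) finite_aggregation(1, re, m), numeric(1))
    expect_true(all(diff(vals) >= 0))
    raw <- converged_aggregation(1, re, Inf, clamp = FALSE)
    expect_lt(abs(vals[length(vals)] - raw), 1e-6)
  }
})

test_that("converged aggregation follows tau(1-re)/re with saturation clamp", {
  expect_equal(converged_aggregation(1, 0.5, 80), 1)
  expect_equal(converged_aggregation(1, 0.02, 80), 49)
  expect_equal(converged_aggregation(1, 0.01, 80), 80)
  expect_equal(converged_aggregation(1, 0.01, 80, clamp = FALSE), 99)
  expect_error(converged_aggregation(1, 0, 80), "diverges")
  # strictly decreasing in re before clamping
  res <- seq(0.01, 1, by = 0.01)
  raw <- vapply(res, function(r) converged_aggregation(1, r, 80,
                                                       clamp = FALSE),
                numeric(1))
  expect_true(all(diff(raw) < 0))
})

test_that("depletion time solves sigma0 (1-re)^D = 1 and decreases with re", {
  expect_identical(depletion_time(1, 0.02), 0)
  expect_identical(depletion_time(0.5, 0.02), 0)
  expect_equal(depletion_time(49, 0.02), 192.64, tolerance = 0.001)
  expect_equal(depletion_time(80, 0.19), 20.795, tolerance = 0.001)
  # defining property
  D <- depletion_time(49, 0.02)
  expect_equal(49 * (1 - 0.02)^D, 1)
  # monotone decline with re
  Ds <- vapply(seq(0.01, 0.9, by = 0.01),
               function(r) depletion_time(49, r), numeric(1))
  expect_true(all(diff(Ds) < 0))
  expect_error(depletion_time(0, 0.02), "sigma0")
  expect_error(depletion_time(49, 1), "re")
})

test_that("traversal time is distance over velocity", {
  expect_equal(min_traversal_time(1, 0.15), 1 / 0.15)
  expect_identical(trunc(min_traversal_time(1, 0.15) * 100) / 100, 6.66)
  expect_equal(min_traversal_time(1, 1), 1)
  expect_equal(min_traversal_time(2, 0.15), 2 * min_traversal_time(1, 0.15))
  expect_error(min_traversal_time(0, 0.5), "distance")
  expect_error(min_traversal_time(1, 0), "velocity")
})

test_that("the minimal-state boundary is the root of the decay condition", {
  r <- minimal_state_boundary(1, 0.15)
  expect_equal(round(r, 2), 0.19)
  # defining property at the returned root
  expect_lt(abs(1 * (1 - r)^(1 + 1 / 0.15) / r - 1), 1e-6)
  # independent dense-grid oracle for a second parameter set
  f <- function(x) (1 - x)^(1 + 1 / 0.3) / x - 1
  grid <- seq(1e-4, 0.999, by = 1e-5)
  fg <- f(grid)
  oracle <- grid[which.min(abs(fg))]
  r2 <- minimal_state_boundary(1, 0.3)
  expect_lt(abs(r2 - oracle), 2e-5)
  expect_equal(round(r2, 3), round(oracle, 3))
  # cross-check the bisection against stats::uniroot
  ur <- stats::uniroot(function(x) (1 - x)^(1 + 1 / 0.15) / x - 1,
                       c(1e-6, 1 - 1e-6), tol = 1e-10)$root
  expect_equal(r, ur, tolerance = 1e-6)
})

test_that("the inactive-state boundary and saturating emission are inverses", {
  expect_equal(inactive_state_boundary(1, 80), 1 / 81)
  expect_equal(round(inactive_state_boundary(1, 80), 3), 0.012)
  expect_equal(inactive_state_boundary(80, 80), 0.5)
  expect_equal(round(saturation_tau(0.02, 80), 2), 1.63)
  expect_equal(saturation_tau(0.5, 80), 80)
  # converged aggregation at the boundary equals saturation exactly
  b <- inactive_state_boundary(1, 80)
  expect_equal(converged_aggregation(1, b, 80, clamp = FALSE), 80)
  # mutual inverses across a grid
  for (re in c(0.005, 0.02, 0.1, 0.3, 0.7)) {
    expect_equal(inactive_state_boundary(saturation_tau(re, 80), 80), re,
                 tolerance = 1e-10)
  }
})

test_that("the three communication states partition the evaporation axis", {
  labels <- vapply(c(0.001, 0.012, 0.02, 0.19, 0.5, 1.0),
                   function(r) classify_state(r)$label, character(1))
  expect_identical(labels, c("inactive", "active", "active", "active",
                             "minimal", "minimal"))
  st <- classify_state(0.02)
  expect_lt(st$boundary_inactive, st$boundary_minimal)
  expect_equal(st$boundary_minimal_used, 0.19)
  expect_equal(st$boundary_inactive_used, 0.012)
  # raw-root comparison is available too
  expect_identical(classify_state(0.012, digits = c(Inf, Inf))$label,
                   "inactive")
  expect_error(classify_state(0.02, tau = 80, sigma_sat = 1e-3),
               "active window")
})

test_that("the analytics report bundles consistent quantities", {
  rep <- analytics_report(0.02)
  expect_identical(rep$state, "active")
  expect_equal(rep$converged_aggregation, 49)
  expect_equal(rep$converged_aggregation_raw, 49)
  expect_equal(rep$depletion_time, depletion_time(49, 0.02))
  expect_equal(round(rep$saturation_tau, 2), 1.63)
  rep2 <- analytics_report(0.001)
  expect_identical(rep2$state, "inactive")
  expect_equal(rep2$converged_aggregation, 80)
  expect_gt(rep2$converged_aggregation_raw, 80)
})
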
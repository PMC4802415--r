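test_that("a single-point sweep returns the steady state of its branch", {
  nw <- default_network()
  # grid of length 1 is a degenerate sweep: strictly-increasing check
  # allows it, and the result equals the relaxed branch state
  sw <- sweep1d(nw, "u", 100, "forward")
  expect_equal(nrow(sw), 1)
  expect_true(sw$converged)
  ss <- find_steady_states(build_network(nw$abundances, nw$kinetics,
                                         u = 100), n_starts = 10, seed = 1)
  rho <- vapply(ss, function(s) s$state[["RhoA_GTP"]], numeric(1))
  expect_true(any(abs(rho - sw$RhoA_GTP) < 1e-4 * max(rho)))
})

test_that("broken-feedback kinetics give coincident branches and no thresholds", {
  nw <- build_network(default_abundances(), monostable_kinetics(), u = 0)
  h <- hysteresis(nw, "u", seq(0, 1500, length.out = 25))
  expect_false(h$bistable)
  expect_true(is.na(h$T1) && is.na(h$T2))
  expect_equal(h$forward$RhoA_GTP, h$backward$RhoA_GTP, tolerance = 1e-4)
})

test_that("the calibrated inhibitor response is hysteretic with T2 < T1", {
  nw <- default_network()
  h <- hysteresis(nw, "u", default_u_grid())
  expect_true(h$bistable)
  expect_lt(h$T2, h$T1)
  # RhoA switches up on the forward sweep (branches are reported in
  # ascending grid order, so the backward drop at T2 also appears as a
  # positive grid-order step)
  expect_gt(h$jumps$RhoA_GTP$forward$size, 0)
  expect_gt(h$jumps$RhoA_GTP$backward$size, 0)
  # Rac1 mirrors RhoA: jumps at the same doses with opposite sign
  expect_lt(h$jumps$Rac1_GTP$forward$size, 0)
  expect_lt(h$jumps$Rac1_GTP$backward$size, 0)
  step <- median(diff(h$grid))
  expect_lt(abs(h$jumps$Rac1_GTP$forward$location - h$T1), step + 1e-9)
  expect_lt(abs(h$jumps$Rac1_GTP$backward$location - h$T2), step + 1e-9)

  # branch monotonicity: RhoA_GTP non-decreasing, Rac1_GTP non-increasing
  # in u along each stable branch (away from the switch points)
  fw_low <- h$forward[h$grid < h$T1 - step, ]
  expect_true(all(diff(fw_low$RhoA_GTP) > -1e-6))
  expect_true(all(diff(fw_low$Rac1_GTP) < 1e-6))
  bw_high <- h$backward[h$grid > h$T2 + step, ]
  expect_true(all(diff(bw_high$RhoA_GTP) > -1e-6))
  expect_true(all(diff(bw_high$Rac1_GTP) < 1e-6))
})

test_that("sweep thresholds agree with bisection on the stable-state count", {
  nw <- default_network()
  grid <- default_u_grid()
  h <- hysteresis(nw, "u", grid)
  rng <- bistable_range(nw, "u", 0, max(grid), rtol = 1e-3, n_starts = 8)
  expect_false(is.null(rng))
  step <- median(diff(grid))
  expect_lt(abs(h$T2 - rng[["lower"]]), step)
  expect_lt(abs(h$T1 - rng[["upper"]]), step)
})

test_that("a 1x1 region map reproduces dynamics_class", {
  nw <- default_network()
  rm1 <- region2d(nw, "rac1_tot", "rhoa_tot", 400, 500, n_starts = 8)
  expect_equal(as.vector(rm1$labels), dynamics_class(nw, n_starts = 8))
})

test_that("hysteresis table export is tidy", {
  nw <- build_network(default_abundances(), monostable_kinetics(), u = 0)
  h <- hysteresis(nw, "u", seq(0, 1500, length.out = 25))
  df <- as.data.frame(h)
  expect_setequal(names(df), c("param_name", "param_value", "branch",
                               "readout", "value", "converged"))
  expect_equal(nrow(df), 25 * 2 * 2)
})

test_that("calibration returns a qualifying midpoint immediately", {
  box <- default_kinetics_box()
  kin <- calibrate_bistable_defaults(box, default_abundances(),
                                     default_u_grid(), seed = 1,
                                     max_iter = 1)
  expect_equal(as.numeric(kin), as.numeric(default_kinetics()),
               tolerance = 1e-12)
  h <- attr(kin, "hysteresis")
  expect_true(h$bistable)
})

test_that("calibration reports failure on a hopeless box", {
  k0 <- unclass(zero_kinetics())
  box <- list(lo = setNames(as.numeric(k0), kinetics_names()),
              hi = setNames(as.numeric(k0), kinetics_names()))
  expect_error(
    calibrate_bistable_defaults(box, default_abundances(),
                                default_u_grid(25), seed = 1, max_iter = 2),
    "widen")
})
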
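test_that("schedules implement first-order washout analytically", {
  pp <- protocol_params(dose_max = 3000, t_half = 3.5)
  naive0 <- make_schedule("naive", 0, pp)
  expect_equal(schedule_u(naive0, seq(0, 40, 10)), rep(0, 5))

  # pretreated arm, dose 0: u relaxes from the pretreat level with
  # half-life t_half; 10 min after the switch the residual is 2^(-10/3.5)
  pre <- make_schedule("pretreated", 0, pp)
  u20 <- schedule_u(pre, 20)
  u30 <- schedule_u(pre, 30)
  expect_equal(u30 / u20, 2^(-10 / 3.5), tolerance = 1e-10)

  # with the upper printed half-life of 5 min, the 10-min residual is 25%
  pp5 <- protocol_params(dose_max = 3000, t_half = 5)
  pre5 <- make_schedule("pretreated", 0, pp5)
  expect_equal(schedule_u(pre5, 30) / schedule_u(pre5, 20), 0.25,
               tolerance = 1e-12)

  expect_error(make_schedule("naive", -1, pp), "dose")
})

test_that("an all-zero schedule leaves the untreated steady state unchanged", {
  nw <- default_network()
  pp <- protocol_params(dose_max = 3000)
  res <- run_protocol(nw, make_schedule("naive", 0, pp))
  base <- untreated_state(nw)
  expect_equal(unname(res$state), unname(base), tolerance = 1e-6)
})

test_that("constant-dose arms settle on the steady-state branch selected by history", {
  nw <- default_network()
  pp <- protocol_params(dose_max = 3000, naive_min = 2000)
  d <- 480   # inside the bistable window
  res <- run_protocol(nw, make_schedule("naive", d, pp))
  ss <- find_steady_states(build_network(nw$abundances, nw$kinetics, u = d),
                           n_starts = 12, seed = 1)
  stable <- Filter(function(s) s$stability == "stable", ss)
  rho <- vapply(stable, function(s) s$state[["RhoA_GTP"]], numeric(1))
  low <- stable[[which.min(rho)]]$state
  expect_lt(state_dist(res$state, low), 1e-2 * sqrt(sum(low^2)))
})

test_that("pretreatment locks the high-RhoA branch inside the window", {
  nw <- default_network()
  pp <- protocol_params(dose_max = 3000)
  d <- 480
  pre <- run_protocol(nw, make_schedule("pretreated", d, pp))
  nai <- run_protocol(nw, make_schedule("naive", d, pp))
  expect_gt(pre$readouts[["RhoA_GTP"]], 5 * nai$readouts[["RhoA_GTP"]])
  expect_lt(pre$readouts[["Rac1_GTP"]], nai$readouts[["Rac1_GTP"]])
})

test_that("instant washout reduces the pretreated arm to a naive arm from the high state", {
  nw <- default_network()
  d <- 480
  pp_fast <- protocol_params(dose_max = 3000, t_half = 1e-6)
  pre <- run_protocol(nw, make_schedule("pretreated", d, pp_fast))
  # naive arm at dose d started from the high-RhoA state, same duration
  nw_max <- build_network(nw$abundances, nw$kinetics, u = 3000)
  high0 <- rhoswitch:::.relax(nw_max,
                              rhoswitch:::state_high_rho(nw_max))$state
  pp_naive <- protocol_params(dose_max = 3000, t_half = 1e-6,
                              naive_min = pp_fast$post_min)
  nai_high <- run_protocol(nw, make_schedule("naive", d, pp_naive),
                           state0 = high0)
  expect_equal(pre$readouts[["RhoA_GTP"]], nai_high$readouts[["RhoA_GTP"]],
               tolerance = 0.05)
})

test_that("sub-threshold pretreatment produces no hysteresis gap", {
  nw <- default_network()
  # dose_max below T2 < T1: the pretreatment never leaves the low branch
  pp <- protocol_params(dose_max = 60)
  dr <- dose_response_hysteresis(nw, c(0, 20, 40, 60), pp)
  expect_false(dr$hysteretic)
  expect_lt(max(abs(dr$gap$gap)), 0.05 * max(dr$dynamic_range, 1))
})

test_that("broken-feedback kinetics give gap-free dose responses", {
  nw <- build_network(default_abundances(), monostable_kinetics(), u = 0)
  pp <- protocol_params(dose_max = 3000, naive_min = 80, post_min = 60)
  dr <- dose_response_hysteresis(nw, c(0, 500, 1500, 3000), pp)
  expect_false(dr$hysteretic)
})

test_that("naive and pretreated arms produce the expected hysteresis loop", {
  nw <- default_network()
  pp <- protocol_params(dose_max = 3000, naive_min = 80, post_min = 60)
  doses <- c(0, 300, 480, 700, 1500, 3000)
  dr <- dose_response_hysteresis(nw, doses, pp)
  expect_true(dr$hysteretic)
  expect_true(all(dr$gap$gap > -1e-6))   # pretreated RhoA >= naive RhoA
  # arms agree at both ends
  cv <- dr$curves
  at <- function(arm, d, r) cv[cv$arm == arm & cv$dose == d, r]
  expect_equal(at("pretreated", 3000, "RhoA_GTP"),
               at("naive", 3000, "RhoA_GTP"), tolerance = 0.01)
  expect_equal(at("pretreated", 0, "RhoA_GTP"),
               at("naive", 0, "RhoA_GTP"), tolerance = 0.05)
  # Rac1 mirrors RhoA: pretreated below naive inside the window
  expect_lt(at("pretreated", 480, "Rac1_GTP"), at("naive", 480, "Rac1_GTP"))
})
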
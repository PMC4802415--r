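test_that("zero kinetics freeze the system; states are marginal", {
  nw <- build_network(default_abundances(), zero_kinetics(), u = 0)
  x0 <- random_state(nw, 2)
  tr <- simulate_network(nw, x0, t_end = 100, dt = 50)
  expect_equal(unname(tr[nrow(tr), species_names()]), unname(x0),
               tolerance = 1e-10)
  cls <- classify_stability(nw, x0)
  expect_equal(cls$stability, "marginal")
  expect_equal(cls$leading_eigenvalue, 0, tolerance = 1e-8)
  expect_equal(dynamics_class(nw, n_starts = 4), "other")
})

test_that("the default network relaxes to quiescence from the inactive corner", {
  nw <- default_network()
  rl <- rhoswitch:::.relax(nw, state_inactive(nw), t_max = 1e4)
  expect_true(rl$converged)
  expect_lt(max(abs(rhs(rl$state, nw))), 1e-8)
})

test_that("the bistable window holds two stable states and one saddle", {
  nw <- default_network(u = 480)
  ss <- find_steady_states(nw, n_starts = 20, seed = 1)
  stab <- vapply(ss, function(s) s$stability, character(1))
  expect_length(ss, 3)
  expect_equal(sum(stab == "stable"), 2)
  expect_equal(sum(stab == "unstable"), 1)
  expect_true(all(vapply(ss, function(s) s$residual, numeric(1)) < 1e-8))

  # anti-correlation: the high-RhoA state has the lower Rac1-GTP
  stable <- ss[stab == "stable"]
  rho <- vapply(stable, function(s) s$state[["RhoA_GTP"]], numeric(1))
  rac <- vapply(stable, function(s) s$state[["Rac1_GTP"]], numeric(1))
  expect_true(rac[which.max(rho)] < rac[which.min(rho)])
})

test_that("stability labels agree with perturbation dynamics", {
  nw <- default_network(u = 480)
  ss <- find_steady_states(nw, n_starts = 20, seed = 1)
  stab <- vapply(ss, function(s) s$stability, character(1))
  stable <- ss[stab == "stable"]
  saddle <- ss[stab == "unstable"][[1]]

  set.seed(42)
  for (s in stable) {
    x <- s$state
    pert <- x * (1 + 0.01 * runif(14, -1, 1))
    pert <- rhoswitch:::project_state(pert, nw)
    rl <- rhoswitch:::.relax(nw, pert, t_max = 2e4)
    expect_lt(state_dist(rl$state, x), 1e-3 * sqrt(sum(x^2)))
  }

  # a perturbation of the saddle towards either stable state diverges to it
  for (s in stable) {
    dir <- s$state - saddle$state
    pert <- saddle$state + 0.01 * dir
    rl <- rhoswitch:::.relax(nw, pmax(pert, 0), t_max = 5e4)
    expect_lt(state_dist(rl$state, s$state),
              0.05 * sqrt(sum(s$state^2)))
  }
})

test_that("classify_stability rejects non-steady input", {
  nw <- default_network()
  expect_error(classify_stability(nw, state_inactive(nw)), "not steady")
})

test_that("reduced eigenvalues match the non-conserved spectrum of the full system", {
  nw <- default_network(u = 480)
  ss <- find_steady_states(nw, n_starts = 12, seed = 1)
  s <- ss[[1]]$state
  # full 14x14 Jacobian by central differences
  J <- matrix(0, 14, 14)
  for (j in 1:14) {
    h <- 1e-6 * max(abs(s[j]), 1)
    xp <- s; xp[j] <- s[j] + h
    xm <- s; xm[j] <- s[j] - h
    J[, j] <- (rhoswitch:::.rhs_raw(xp, nw) -
               rhoswitch:::.rhs_raw(xm, nw)) / (2 * h)
  }
  lam_full <- sort(Re(eigen(J, only.values = TRUE)$values))
  # six conservation laws contribute six (numerically) zero eigenvalues
  expect_equal(sum(abs(lam_full) < 1e-6), 6)
  lam_red <- eigen(reduced_jacobian(nw, s), only.values = TRUE)$values
  expect_equal(max(Re(lam_red)),
               max(lam_full[abs(lam_full) >= 1e-6]), tolerance = 1e-4)
})

test_that("dynamics classes at the calibrated defaults follow the inhibitor level", {
  expect_equal(dynamics_class(default_network(u = 0)), "monostable")
  expect_equal(dynamics_class(default_network(u = 480)), "bistable")
  expect_equal(dynamics_class(default_network(u = 2500)), "monostable")
})

test_that("stable-state sets match brute-force integration on random networks", {
  # scaled-down version of the full oracle-equivalence suite (see
  # test-acceptance.R); 5 networks, 60 brute-force starts each
  for (seed in 1:5) {
    nw <- random_network(seed)
    ss <- find_steady_states(nw, n_starts = 20, seed = seed)
    stable <- Filter(function(s) s$stability == "stable", ss)
    bf <- brute_force_stable_states(nw, n_starts = 60, seed = seed)
    expect_equal(length(stable), length(bf))
    scale <- max(sqrt(sum(as.numeric(nw$abundances)^2)), 1)
    for (b in bf) {
      d <- vapply(stable, function(s) state_dist(s$state, b) / scale,
                  numeric(1))
      expect_lt(min(d), 1e-3)
    }
  }
})

test_that("fixed-point counts are odd for non-degenerate networks", {
  for (u in c(0, 480, 2500)) {
    ss <- find_steady_states(default_network(u = u), n_starts = 16, seed = 2)
    expect_true(length(ss) %in% c(1, 3))
  }
})
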
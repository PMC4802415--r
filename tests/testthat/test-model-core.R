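test_that("network construction validates inputs and conservation", {
  nw <- default_network()
  expect_s3_class(nw, "rr_network")
  expect_length(species_names(), 14)
  expect_equal(ncol(nw$stoichiometry), 14)

  # every moiety mask is orthogonal to every stoichiometry column
  for (m in names(nw$masks)) {
    expect_equal(as.numeric(nw$masks[[m]] %*% nw$stoichiometry),
                 rep(0, 14), tolerance = 0)
  }

  ab_bad <- unclass(default_abundances()); ab_bad["rac1_tot"] <- -1
  expect_error(build_network(structure(ab_bad, class = "rr_abundances"),
                             default_kinetics()), "rac1_tot")
  k_bad <- unclass(default_kinetics()); k_bad["Km_r1"] <- 0
  expect_error(kinetics(k_bad), "Km_r1")
  expect_error(build_network(default_abundances(), default_kinetics(),
                             u = -5), "u")
})

test_that("rhs vanishes at the zero state and respects conservation", {
  nw <- default_network(u = 120)
  zero <- setNames(rep(0, 14), species_names())
  expect_equal(unname(rhs(zero, nw)), rep(0, 14))

  for (seed in 1:5) {
    x <- random_state(nw, seed)
    dx <- rhs(x, nw)
    for (m in names(nw$masks)) {
      expect_lt(abs(sum(nw$masks[[m]] * dx)), 1e-10)
    }
  }
  expect_error(rhs(setNames(rep(-1, 14), species_names()), nw), "negative")
})

test_that("single-reaction flux matches the hand-computed mass-action rate", {
  # only PAK binding active: d(cPAK)/dt = kon_pak * Rac1_GTP * iPAK
  k <- unclass(zero_kinetics())
  k["kon_pak"] <- 0.004
  nw <- build_network(default_abundances(), kinetics(k), u = 0)
  x <- setNames(rep(0, 14), species_names())
  x["Rac1_GTP"] <- 10; x["iPAK"] <- 20
  dx <- rhs(x, nw)
  expect_equal(dx[["cPAK"]], 0.004 * 10 * 20)
  expect_equal(dx[["Rac1_GTP"]], -0.004 * 200)
  expect_equal(dx[["iPAK"]], -0.004 * 200)
  expect_equal(sum(abs(dx[setdiff(species_names(),
                                  c("cPAK", "Rac1_GTP", "iPAK"))])), 0)
})

test_that("moiety totals follow species membership", {
  zero <- setNames(rep(0, 14), species_names())
  expect_equal(unname(moiety_totals(zero)), rep(0, 6))
  x <- zero; x["cPAK"] <- 5
  tot <- moiety_totals(x)
  expect_equal(tot[["rac1_tot"]], 5)   # the complex carries one Rac1
  expect_equal(tot[["pak_tot"]], 5)    # and one PAK
  expect_equal(tot[["rhoa_tot"]], 0)
})

test_that("R and compiled right-hand sides produce identical dynamics", {
  nw <- default_network(u = 300)
  rhs_r <- function(t, y, parms) list(unname(rhs(setNames(y, species_names()),
                                                 nw)))
  for (seed in 1:3) {
    x0 <- random_state(nw, seed + 40)
    out_c <- deSolve::ode(y = x0, times = c(0, 10, 30),
                          parms = rhoswitch:::.parms_vector(nw),
                          func = "rhoswitch_derivs",
                          initfunc = "rhoswitch_initmod",
                          dllname = "rhoswitch", method = "lsoda",
                          rtol = 1e-10, atol = 1e-10)
    out_r <- deSolve::ode(y = x0, times = c(0, 10, 30), func = rhs_r,
                          parms = NULL, method = "lsoda",
                          rtol = 1e-10, atol = 1e-10)
    expect_equal(unname(out_c[3, species_names()]),
                 unname(out_r[3, species_names()]), tolerance = 1e-6)
  }
})

test_that("rate laws reduce correctly when the GAP arm is off", {
  k <- unclass(default_kinetics())
  k["Vb_racgap"] <- 0
  nw <- build_network(default_abundances(), kinetics(k), u = 0)
  x <- random_state(nw, 3)
  x["GAPa"] <- 0
  v <- rate_vector(x, nw)
  expect_identical(v[["RAC_DEACT"]], 0)
})

test_that("trajectories conserve moieties and stay nonnegative", {
  for (seed in 1:6) {
    nw <- random_network(seed)
    x0 <- random_state(nw, seed + 100)
    tr <- simulate_network(nw, x0, t_end = 500, dt = 25)
    ref <- moiety_totals(x0)
    for (i in c(2, nrow(tr))) {
      tot <- moiety_totals(tr[i, species_names()])
      expect_equal(unname(tot), unname(ref), tolerance = 1e-6)
    }
    expect_gt(min(tr[, species_names()]), -1e-9)
  }
})

test_that("abundance projection rescales states onto new totals", {
  nw <- default_network()
  x <- random_state(nw, 11)
  nw2 <- rhoswitch:::set_param(nw, "rac1_tot", 700)
  y <- rhoswitch:::project_state(x, nw2)
  expect_equal(unname(moiety_totals(y)),
               unname(as.numeric(nw2$abundances)), tolerance = 1e-9)
})
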
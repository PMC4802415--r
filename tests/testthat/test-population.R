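test_that("population sampling honors cv, medians and determinism", {
  nom <- default_abundances()
  pop0 <- sample_population(nom, cv = 0, n_cells = 5, seed = 1)
  for (f in names(nom)) {
    expect_equal(pop0[[f]], rep(nom[[f]], 5))
  }

  pop_a <- sample_population(nom, cv = 0.3, n_cells = 100, seed = 9)
  pop_b <- sample_population(nom, cv = 0.3, n_cells = 100, seed = 9)
  expect_identical(pop_a, pop_b)
  expect_true(all(unlist(pop_a[names(nom)]) > 0))

  big <- sample_population(nom, cv = 0.3, n_cells = 10000, seed = 2)
  for (f in c("rac1_tot", "gefh1_tot")) {
    expect_lt(abs(median(big[[f]]) - nom[[f]]) / nom[[f]], 0.05)
  }
})

test_that("noise-free readouts of identical cells are deterministic", {
  pop <- sample_population(default_abundances(), cv = 0, n_cells = 3,
                           seed = 1)
  pp <- protocol_params(dose_max = 3000)
  sch <- make_schedule("naive", 480, pp)
  rd <- population_readouts(pop, sch, default_kinetics(), noise_cv = 0,
                            seed = 1)
  expect_equal(attr(rd, "n_dropped"), 0)
  expect_equal(rd$value, rep(rd$value[1], 3))
  ref <- run_protocol(default_network(), sch)$readouts[["RhoA_GTP"]]
  expect_equal(rd$value[1], ref, tolerance = 1e-8)
})

test_that("bimodality verdicts on constructed mixtures are correct and seed-stable", {
  expect_error(bimodality_test(rexp(10) + 1), ">= 50")
  for (seed in 1:5) {
    set.seed(seed)
    uni <- exp(rnorm(500, 1, 0.3))
    expect_equal(bimodality_test(uni)$verdict, "unimodal")
    mix <- exp(c(rnorm(250, 0, 0.5), rnorm(250, 3, 0.5)))  # 6 SDs apart
    bt <- bimodality_test(mix)
    expect_equal(bt$verdict, "bimodal")
    expect_gt(bt$separation, 2)
    expect_gt(bt$delta_bic, 10)
  }
})

test_that("zero-noise parameter fit recovers the truth with zero residual", {
  nw <- default_network()
  pp <- protocol_params(dose_max = 3000)
  doses <- c(0, 400, 800, 2000, 3000)
  ds <- synthetic_dose_response(nw, doses, pp, noise_cv = 0, n_reps = 3,
                                seed = 1)
  truth <- c(kcat_gef = 12, kon_i = 0.0045)
  bounds <- list(lo = truth / 2, hi = truth * 2)
  # the multistart midpoint of a symmetric box is the truth itself
  fit <- fit_parameters(ds, names(truth), bounds, nw, pp,
                        n_multistart = 1, seed = 1)
  expect_equal(unname(fit$estimates), unname(truth), tolerance = 1e-4)
  expect_lt(fit$residual_norm, 1e-4)
})

test_that("recovery error grows monotonically with observation noise", {
  nw <- default_network()
  pp <- protocol_params(dose_max = 3000)
  doses <- c(0, 200, 400, 600, 800, 1200, 2000, 3000)
  truth <- c(kcat_gef = 12, kon_i = 0.0045)
  bounds <- list(lo = truth / 4, hi = truth * 4)
  mean_err <- vapply(c(0.02, 0.05, 0.1), function(ncv) {
    errs <- vapply(1:10, function(s) {
      ds <- synthetic_dose_response(nw, doses, pp, noise_cv = ncv,
                                    n_reps = 3, seed = s)
      fit <- fit_parameters(ds, names(truth), bounds, nw, pp,
                            n_multistart = 1, seed = s)
      mean(abs(fit$estimates - truth) / truth)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("non-identifiable designs trigger a profile warning", {
  nw <- default_network()
  pp <- protocol_params(dose_max = 3000)
  ds <- synthetic_dose_response(nw, c(0, 400, 800, 3000), pp,
                                noise_cv = 0, n_reps = 3, seed = 1)
  # a naive arm at dose 0 never sees the inhibitor: kon_i has exactly no
  # effect on this design, so its profile is flat
  ds0 <- ds[ds$dose == 0 & ds$arm == "naive", ]
  bounds <- list(lo = c(kon_i = 0.001), hi = c(kon_i = 0.02))
  expect_warning(
    fit_parameters(ds0, "kon_i", bounds, nw, pp, n_multistart = 1,
                   seed = 1),
    "identifiable")
})
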